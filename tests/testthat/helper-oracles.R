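# Independent oracles and small fixture builders used across the suite.

# Brute-force 8-connected labelling by breadth-first flood fill,
# independent of the package's union-find implementation.
oracle_label_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          queue <- c(queue, (cc - 1L) * nr + rr)
        }
      }
    }
  }
  lab
}

# Canonical partition signature of a labelling: components as sorted
# pixel-index sets, ordered by their smallest pixel. Two labelings are
# equivalent iff their signatures are identical.
partition_signature <- function(lab) {
  fg <- which(lab > 0L)
  if (!length(fg)) return(list())
  comps <- unname(split(fg, lab[fg]))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, numeric(1)))]
}

# Exhaustive pairwise percent agreement by triple loop (objects x rater
# pairs), independent of the package's vectorised computation.
oracle_agreement <- function(df, cls) {
  raters <- sort(unique(df$rater_id))
  objects <- sort(unique(df$object_id))
  num <- 0L; den <- 0L
  for (oi in objects) {
    sub <- df[df$object_id == oi, ]
    for (i in seq_len(length(raters) - 1L)) {
      for (j in (i + 1L):length(raters)) {
        a <- sub$label[sub$rater_id == raters[i]]
        b <- sub$label[sub$rater_id == raters[j]]
        if (length(a) != 1L || length(b) != 1L) next
        if (a == cls || b == cls) {
          den <- den + 1L
          if (a == cls && b == cls) num <- num + 1L
        }
      }
    }
  }
  if (den == 0L) NA_real_ else 100 * num / den
}

# A flat-background RGB test image with given green/red values over a
# pixel-index set.
make_test_fov <- function(nr = 32, nc = 32, idx = integer(),
                          r_val = 0L, g_val = 0L, b_val = 0L,
                          bg = 0L, bit_depth = 8L, pixel_size_um = 1,
                          exposure_class = "low") {
  px <- array(bg, c(nr, nc, 3))
  ch <- matrix(bg, nr, nc)
  ch[idx] <- r_val; px[, , 1] <- ch
  ch <- matrix(bg, nr, nc)
  ch[idx] <- g_val; px[, , 2] <- ch
  ch <- matrix(bg, nr, nc)
  ch[idx] <- b_val; px[, , 3] <- ch
  fov_image(px, bit_depth, pixel_size_um, exposure_class)
}

# Pixel indices of a rasterised disk (pixel centres within radius).
disk_idx <- function(nr, nc, cr, cc, radius) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  which((rows - cr)^2 + (cols - cc)^2 <= radius^2)
}

# Small unanimous rating table.
make_unanimous_ratings <- function(labels, raters = c("A", "B", "C")) {
  do.call(rbind, lapply(raters, function(r) {
    data.frame(object_id = sprintf("o%02d", seq_along(labels)),
               rater_id = r, label = labels, stringsAsFactors = FALSE)
  }))
}
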