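# Independent reference implementations used as oracles. These share
# no code with the package internals: labeling is done by iterative
# minimum-label propagation (the package uses a depth-first flood
# fill in C++), sums by explicit per-pixel loops.

# Connected-component labeling by min-label propagation to a fixpoint,
# then renumbering by first-encountered pixel in row-major order.
label_oracle <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))  # unique seed labels (column-major ok)
  shifts <- if (connectivity == 8)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  repeat {
    new <- lab
    for (s in shifts) {
      shifted <- shift_matrix(lab, s[1], s[2])
      upd <- mask & shifted > 0 & (new == 0 | shifted < new)
      new[upd] <- shifted[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  renumber_row_major(lab)
}

shift_matrix <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

renumber_row_major <- function(lab) {
  tl <- t(lab)
  first_seen <- unique(as.vector(tl)[as.vector(tl) > 0])
  out <- lab
  for (k in seq_along(first_seen)) out[lab == first_seen[k]] <- k
  out
}

random_mask <- function(h, w, p = 0.4, seed = 1) {
  withr::with_seed(seed, matrix(runif(h * w) < p, h, w))
}

random_image <- function(h, w, seed = 1) {
  withr::with_seed(seed, two_channel_image(
    matrix(sample(0:255, h * w, replace = TRUE), h, w),
    matrix(sample(0:255, h * w, replace = TRUE), h, w)))
}

# raw integrated density by explicit loop
rid_loop <- function(channel, pixels) {
  total <- 0
  for (k in seq_len(nrow(pixels)))
    total <- total + channel[pixels[k, 1], pixels[k, 2]]
  total
}

# merged gray by explicit per-pixel loop, half-up rounding
merge_loop <- function(img) {
  h <- nrow(img$red); w <- ncol(img$red)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- as.integer(min(255, floor((img$red[i, j] + img$green[i, j]) / 2 + 0.5)))
  out
}

# Otsu by direct minimization of pooled within-class variance over all
# pixel values (not histogram moments).
otsu_oracle <- function(gray) {
  v <- as.vector(gray)
  wcv <- vapply(0:254, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) return(Inf)
    vl <- if (length(lo) > 1) var(lo) * (length(lo) - 1) else 0
    vh <- if (length(hi) > 1) var(hi) * (length(hi) - 1) else 0
    (vl + vh) / length(v)
  }, numeric(1))
  (0:254)[which.min(wcv)]
}

# midrank Spearman rho from first principles: explicit average ranks
# by sorting, then the Pearson formula written out
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (u in unique(v)) {
      pos <- which(v == u)
      lower <- sum(v < u)
      r[pos] <- mean(lower + seq_along(pos))
    }
    r
  }
  a <- midrank(x); b <- midrank(y)
  num <- sum((a - mean(a)) * (b - mean(b)))
  num / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# square block helper for mask construction
put_block <- function(mask, r0, c0, size) {
  mask[r0:(r0 + size - 1), c0:(c0 + size - 1)] <- TRUE
  mask
}

tiny_fdl_configs <- function(seed = 1, n_cells = 6) {
  fdl_group_configs(seed = seed, n_cells = n_cells,
                    image_height_px = 256L, image_width_px = 256L,
                    cell_radius_px_range = c(12L, 15L))
}
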