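# Independent re-implementations used as oracles. These deliberately
# share no code with the package: plain loops instead of the package's
# vectorised primitives.

# Abruptness pipeline (truncation -> smoothing -> differences) on a raw
# bottom-to-top canopy vector. Returns NULL if no belt exceeds the
# cutoff.
oracle_abruptness <- function(v, cutoff = 3) {
  n <- length(v)
  y_t <- NA_integer_
  for (i in seq_len(n)) if (v[i] > cutoff) y_t <- i
  if (is.na(y_t)) return(NULL)
  tv <- v
  for (i in seq_len(n)) if (i <= y_t) tv[i] <- v[y_t]
  sv <- tv
  i <- n - 1L
  while (i >= y_t + 1L) {
    if (sv[i + 1L] > sv[i]) sv[i] <- sv[i + 1L]
    i <- i - 1L
  }
  d <- numeric(n - 1L)
  for (y in seq_len(n - 1L)) d[y] <- sv[y + 1L] - sv[y]
  list(y_t = y_t, truncated = tv, smoothed = sv,
       a_abr = -min(d), n_abr = -min(d) / max(v))
}

# Belt-wise first and second maxima of subplot canopy heights by an
# O(n^2) per-belt rescan of the raw tree list.
oracle_belt_max <- function(trees, spec) {
  nb <- spec$n_belts; ns <- spec$subplots_per_belt
  max1 <- max2 <- numeric(nb)
  for (b in seq_len(nb)) {
    canopies <- c()
    for (s in seq_len(ns)) {
      best <- NA_real_
      for (k in seq_len(nrow(trees))) {
        bi <- min(floor(trees$y[k] / spec$belt_width) + 1, nb)
        si <- min(floor(trees$x[k] / spec$subplot_size) + 1, ns)
        if (bi == b && si == s && trees$height[k] > spec$seedling_cutoff)
          if (is.na(best) || trees$height[k] > best) best <- trees$height[k]
      }
      if (!is.na(best)) canopies <- c(canopies, best)
    }
    canopies <- sort(canopies, decreasing = TRUE)
    if (length(canopies) >= 1) max1[b] <- canopies[1]
    if (length(canopies) >= 2) max2[b] <- canopies[2]
  }
  list(max1 = max1, max2 = max2)
}

# random raw canopy vector emulating a treeline profile, for the
# abruptness equivalence scan
random_canopy_vector <- function(n) {
  base <- sort(runif(n, 0, 12), decreasing = TRUE)
  base[runif(n) < 0.2] <- 0              # gaps
  round(base, 2)
}

make_trees <- function(x, y, height, crown_diameter = NULL,
                       growth_form = NULL, spec,
                       crown_ratio = 0.5) {
  df <- data.frame(x = x, y = y, height = height)
  if (!is.null(crown_diameter)) df$crown_diameter <- crown_diameter
  if (!is.null(growth_form)) df$growth_form <- growth_form
  as_tree_records(df, spec, crown_ratio = crown_ratio)
}
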