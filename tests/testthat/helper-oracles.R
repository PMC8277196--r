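# Independent reference implementations used to cross-check the package.
# These are deliberately naive (loops, recursion) and share no code with
# the implementations they verify.

# flat grayscale erosion/dilation by brute force; out-of-image neighbours
# are ignored (neighbourhood intersected with the image domain)
oracle_morph <- function(px, kern, fun) {
  nr <- nrow(px); nc <- ncol(px)
  kr <- (nrow(kern) - 1) / 2; kc <- (ncol(kern) - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(0)
    for (a in -kr:kr) for (b in -kc:kc) {
      if (kern[a + kr + 1, b + kc + 1] == 0) next
      ii <- i + a; jj <- j + b
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      vals <- c(vals, px[ii, jj])
    }
    out[i, j] <- fun(vals)
  }
  out
}

# white top-hat = img - (dilate(erode(img)))
oracle_top_hat <- function(px, radius_px) {
  kern <- punctakit::disc_kernel(radius_px)
  opened <- oracle_morph(oracle_morph(px, kern, min), kern, max)
  out <- px - opened
  out[out < 0] <- 0
  out
}

# recursive flood-fill labeling
oracle_label <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  fill <- function(i, j, lab) {
    if (i < 1 || i > nr || j < 1 || j > nc) return(invisible())
    if (!mask[i, j] || labels[i, j] != 0L) return(invisible())
    labels[i, j] <<- lab
    for (o in offs) fill(i + o[1], j + o[2], lab)
  }
  lab <- 0L
  for (idx in which(mask)) {
    if (labels[idx] != 0L) next
    lab <- lab + 1L
    fill(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L, lab)
  }
  labels
}

# canonical relabeling by first occurrence, so two labelings compare as
# partitions regardless of label order
canonical_labels <- function(labels) {
  seen <- unique(labels[labels > 0])
  out <- labels
  for (k in seq_along(seen)) out[labels == seen[k]] <- k
  out
}

# textbook two-pass Pearson: means first, then covariance/variances
oracle_pearson <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# pooled-variance two-sample t statistic and two-sided p, by the formulas
oracle_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(statistic = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# one-way ANOVA F from explicit sums of squares
oracle_anova_f <- function(values, groups) {
  gm <- mean(values)
  lev <- unique(groups)
  ssb <- sum(vapply(lev, function(l) {
    n <- sum(groups == l); n * (mean(values[groups == l]) - gm)^2
  }, 1))
  ssw <- sum(vapply(lev, function(l) {
    sum((values[groups == l] - mean(values[groups == l]))^2)
  }, 1))
  dfb <- length(lev) - 1; dfw <- length(values) - length(lev)
  (ssb / dfb) / (ssw / dfw)
}

# greedy matching of detected puncta to ground-truth records by centroid
match_truth <- function(table, truth) {
  if (nrow(table) == 0 || nrow(truth) == 0) return(integer(0))
  d2 <- outer(table$centroid_x_um, truth$x_um, "-")^2 +
    outer(table$centroid_y_um, truth$y_um, "-")^2
  apply(d2, 1, which.min)
}
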