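# Shared fixture builders. Everything is generated in code at test time.

# straight tube of given radius/length rasterized at isotropic spacing
tube_fixture <- function(radius = 2, length = 20, spacing = 0.5,
                         shape = c(64, 64, 64), start = NULL) {
  centre <- (shape - 1) * spacing / 2
  if (is.null(start)) start <- c(centre[1] - length / 2, centre[2], centre[3])
  tree <- vessel_tree(list(make_parametric_centerline(
    "line", list(length = length, start = start), min(1, spacing * 2))))
  ras <- rasterize_tree(tree, radius, rep(spacing, 3), shape)
  list(tree = tree, mask = ras$truth_vessel_mask, volume = ras$volume,
       axis_y = centre[2], axis_z = centre[3],
       x_range = c(start[1], start[1] + length))
}

# Y-shaped tree: trunk plus two symmetric children, one bifurcation
y_fixture <- function(radius = 1.5, spacing = 0.5, shape = c(64, 64, 64)) {
  b1 <- make_parametric_centerline("line", list(length = 12, start = c(5, 16, 16)), 0.5)
  ang <- pi / 5
  b2 <- make_parametric_centerline("line", list(
    length = 10, start = c(17, 16, 16), direction = c(cos(ang), sin(ang), 0)), 0.5)
  b3 <- make_parametric_centerline("line", list(
    length = 10, start = c(17, 16, 16), direction = c(cos(ang), -sin(ang), 0)), 0.5)
  tree <- vessel_tree(list(b1, b2, b3), bifurcations = matrix(c(17, 16, 16), 1))
  ras <- rasterize_tree(tree, radius, rep(spacing, 3), shape)
  list(tree = tree, mask = ras$truth_vessel_mask)
}

# brute-force pairwise AUC oracle
auc_brute <- function(labels, scores) {
  pos <- if (is.logical(labels) || is.numeric(labels)) {
    labels == max(labels)
  } else as.character(labels) == sort(unique(as.character(labels)))[1]
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# mutual information oracle via the entropy identity H(x) + H(y) - H(x,y)
mi_entropy_oracle <- function(x, y) {
  H <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  H(x) + H(y) - H(paste(x, y))
}

# ICC(2,1) oracle via two-way ANOVA mean squares (aov)
icc_aov_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(value = c(x, y),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(value ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# curvature via the circumradius R = abc / (4A), area by Heron's formula
menger_heron_oracle <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p1)^2)); b <- sqrt(sum((p3 - p2)^2)); cl <- sqrt(sum((p3 - p1)^2))
  s <- (a + b + cl) / 2
  A2 <- s * (s - a) * (s - b) * (s - cl)
  if (A2 <= 0) return(0)
  4 * sqrt(A2) / (a * b * cl)
}
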