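# Mutant-versus-wild-type response machinery: baseline profiles, normalized
# deltas, five-bin classification, chi-square against the Gaussian null,
# stratified response ratios and B-factor normalization.

.BIN_LEVELS <- c("large_rigid", "moderate_rigid", "no_change",
                 "moderate_flex", "large_flex")

#' Position-wise baseline over a wild-type profile set
#'
#' Mean and standard deviation per position (or per pixel, for flattened
#' matrices) over a set of aligned equal-length profiles.  Values within
#' one standard deviation of the mean are treated as background noise by
#' the downstream classification.  The population (n divisor) standard
#' deviation is used by default — appropriate for a small fixed set of
#' reference structures; set `sample_sd = TRUE` for the n-1 divisor.
#'
#' @param profiles List of equal-length numeric vectors (or matrices of
#'   identical shape), or a matrix with one profile per row.
#' @param sample_sd Use the sample (n-1) standard deviation instead.
#' @return A `dcm_baseline`: list with `mean`, `sigma`, `n_structures`,
#'   `dim` (original shape, if profiles were matrices).
#' @export
baseline <- function(profiles, sample_sd = FALSE) {
  if (is.matrix(profiles)) {
    profiles <- lapply(seq_len(nrow(profiles)), function(i) profiles[i, ])
  }
  stopifnot(length(profiles) >= 2)
  shape <- dim(profiles[[1]])
  flat <- lapply(profiles, as.vector)
  len <- lengths(flat)
  if (length(unique(len)) != 1) {
    stop("profile shape mismatch: lengths ", paste(unique(len), collapse = ", "))
  }
  m <- do.call(rbind, flat)
  mu <- colMeans(m)
  n <- nrow(m)
  ss <- colSums((m - rep(mu, each = n))^2)
  sigma <- sqrt(ss / if (sample_sd) (n - 1) else n)
  structure(list(mean = mu, sigma = sigma, n_structures = n, dim = shape),
            class = "dcm_baseline")
}

#' @export
print.dcm_baseline <- function(x, ...) {
  cat(sprintf("baseline over %d profiles, %d positions (median sigma %.4g)\n",
              x$n_structures, length(x$mean), median(x$sigma)))
  invisible(x)
}

#' Z-scores of a profile against a baseline
#'
#' Positions with zero baseline sigma get z = 0 when the value equals the
#' mean and a saturated +/- Inf otherwise (flagged via attribute
#' `zero_sigma`).
#'
#' @param value Numeric vector (or matrix) aligned with the baseline.
#' @param base A `dcm_baseline`.
#' @return Numeric vector of signed z-scores.
#' @export
baseline_z <- function(value, base) {
  v <- as.vector(value)
  stopifnot(length(v) == length(base$mean))
  z <- ifelse(base$sigma > 0, (v - base$mean) / base$sigma,
              ifelse(v == base$mean, 0, sign(v - base$mean) * Inf))
  attr(z, "zero_sigma") <- base$sigma == 0
  z
}

#' Noise-thresholded, saturated normalized delta
#'
#' `z = (value - mean)/sigma`; the normalized response is 0 inside the
#' +/-1 sigma noise band, follows `sign(z) * (|z| - 1)` between 1 and 2
#' sigma, and saturates at +/-1 beyond 2 sigma, so all "large" changes map
#' to the same maximum magnitude.
#'
#' @param value Numeric vector (or scalar) of mutant values, or a z-score
#'   vector if `base` is `NULL`.
#' @param base Optional `dcm_baseline` position set (mean/sigma recycled as
#'   needed).
#' @return Values in `[-1, 1]`.
#' @export
normalized_delta <- function(value, base = NULL) {
  z <- if (is.null(base)) value else baseline_z(value, base)
  zs <- ifelse(is.infinite(z), sign(z) * 3, z)  # zero-sigma saturation
  sign(zs) * pmin(pmax(abs(zs) - 1, 0), 1)
}

#' Classify signed z-scores into the five response bins
#'
#' Thresholds at `|z| = 1` and `|z| = 2`; boundary values go to the outer
#' bin.  Positive z means increased flexibility.
#'
#' @param z Signed z-scores.
#' @return Factor with levels `large_rigid`, `moderate_rigid`, `no_change`,
#'   `moderate_flex`, `large_flex`.
#' @export
classify_bins <- function(z) {
  lab <- ifelse(z <= -2, "large_rigid",
         ifelse(z <= -1, "moderate_rigid",
         ifelse(z < 1, "no_change",
         ifelse(z < 2, "moderate_flex", "large_flex"))))
  factor(lab, levels = .BIN_LEVELS)
}

#' Gaussian null expectation for the five response bins
#'
#' Standard-normal band probabilities
#' `[P(z <= -2), P(-2 < z <= -1), P(|z| < 1), P(1 <= z < 2), P(z >= 2)]`.
#'
#' @return Named numeric vector summing to 1.
#' @export
null_expectation <- function() {
  cuts <- c(-Inf, -2, -1, 1, 2, Inf)
  p <- diff(pnorm(cuts))
  names(p) <- .BIN_LEVELS
  p
}

#' Chi-square test of a five-bin histogram against the Gaussian null
#'
#' Pearson chi-square with 4 degrees of freedom; expected counts are the
#' total count times [null_expectation()].
#'
#' @param observed Counts in bin order (`large_rigid` ... `large_flex`), or
#'   a factor/table from [classify_bins()].
#' @return List with `statistic`, `p_value`, `df`, `expected`.
#' @export
chisq_vs_null <- function(observed) {
  if (is.factor(observed)) observed <- table(observed)
  observed <- as.numeric(observed)
  stopifnot(length(observed) == 5, sum(observed) > 0)
  expected <- sum(observed) * null_expectation()
  if (any(expected <= 0)) stop("degenerate expected counts")
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat, p_value = pchisq(stat, df = 4, lower.tail = FALSE),
       df = 4, expected = expected)
}

#' Ratio of changed to unchanged positions
#'
#' The number of positions in the four changed bins divided by the number
#' with no change.
#'
#' @param bins Factor of bin labels, or a numeric vector of 5 counts in bin
#'   order.
#' @return The ratio (0 when everything is unchanged; `NA` with a warning
#'   when there are no unchanged positions).
#' @export
response_ratio <- function(bins) {
  counts <- if (is.numeric(bins) && length(bins) == 5) bins else
    as.numeric(table(factor(bins, levels = .BIN_LEVELS)))
  changed <- sum(counts[-3])
  if (counts[3] == 0) {
    warning("no positions without change; ratio undefined")
    return(NA_real_)
  }
  changed / counts[3]
}

#' Stratified response counts around a mutation site
#'
#' Cross-tabulates per-residue response bins by distance to the mutation
#' site (alpha-carbon to alpha-carbon: 0-8, 8-16, >=16 Angstrom) and by a
#' residue annotation class (solvent accessibility tertile, secondary
#' structure, or subdomain).  The mutated residue itself is excluded.
#'
#' @param bins Factor of per-residue bins (names or order = residue index).
#' @param classes Character/factor of per-residue annotation classes.
#' @param mutation_site Residue index of the mutation.
#' @param ca_coords Matrix (n x 3) of alpha-carbon coordinates in residue
#'   order.
#' @param breaks Distance strata breaks (Angstrom).
#' @param exclude_window Also exclude residues within this many sequence
#'   positions of the mutation site (0 = exclude the site only).
#' @return Tibble of counts per (distance stratum, class, bin) plus the
#'   changed/unchanged `ratio` per stratum-class row set; suitable for
#'   [response_ratio()].
#' @export
stratify <- function(bins, classes, mutation_site, ca_coords,
                     breaks = c(0, 8, 16, Inf), exclude_window = 0) {
  n <- length(bins)
  stopifnot(length(classes) == n, nrow(ca_coords) == n,
            mutation_site >= 1, mutation_site <= n)
  if (any(!is.finite(ca_coords))) stop("missing alpha-carbon coordinates")
  d <- sqrt(rowSums((ca_coords -
                       matrix(ca_coords[mutation_site, ], n, 3,
                              byrow = TRUE))^2))
  lab <- paste0("[", head(breaks, -1), ",", tail(breaks, -1), ")")
  stratum <- cut(d, breaks = breaks, labels = lab, right = FALSE,
                 include.lowest = TRUE)
  keep <- abs(seq_len(n) - mutation_site) > exclude_window
  tab <- as.data.frame(table(
    stratum = stratum[keep],
    class = classes[keep],
    bin = factor(bins[keep], levels = .BIN_LEVELS)))
  tibble::as_tibble(tab) |>
    dplyr::rename(count = "Freq")
}

#' Changed/unchanged ratios from a stratified count table
#'
#' @param counts Output of [stratify()] (or any tibble with `bin` and
#'   `count` plus grouping columns).
#' @param ... Grouping columns (defaults to `stratum` and `class`).
#' @return Tibble of totals and ratios per group.
#' @export
stratum_ratios <- function(counts, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) groups <- rlang::quos(.data$stratum, .data$class)
  counts |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      n = sum(.data$count),
      no_change = sum(.data$count[.data$bin == "no_change"]),
      changed = sum(.data$count[.data$bin != "no_change"]),
      ratio = ifelse(.data$no_change > 0,
                     .data$changed / .data$no_change, NA_real_),
      .groups = "drop")
}

#' Median-based B-factor normalization
#'
#' Robust per-structure standardization of alpha-carbon B-factors:
#' `(B - median(B)) / (1.4826 * median(|B - median(B)|))` (the median
#' absolute deviation with the Gaussian consistency constant).  Affine
#' transforms of the input yield identical output.  A zero spread triggers
#' centering only, with a warning.
#'
#' @param b Numeric vector of positive B-factors (>= 3 values).
#' @return Normalized values.
#' @export
normalize_bfactors_median <- function(b) {
  stopifnot(length(b) >= 3)
  if (any(!is.finite(b)) || any(b <= 0)) {
    stop("B-factors must be positive and finite")
  }
  ctr <- b - median(b)
  spread <- mad(b)  # 1.4826 * median(|B - median|)
  if (spread == 0) {
    warning("zero median spread; centering only")
    return(ctr)
  }
  ctr / spread
}

#' Extract a single-residue strip from a delta-CC matrix
#'
#' @param cc_delta Symmetric matrix of normalized CC changes.
#' @param reference Residue (row) index.
#' @return The reference row as a numeric vector.
#' @export
cc_strip <- function(cc_delta, reference) {
  stopifnot(is.matrix(cc_delta), nrow(cc_delta) == ncol(cc_delta))
  if (reference < 1 || reference > nrow(cc_delta)) {
    stop("reference residue ", reference, " out of range 1..",
         nrow(cc_delta))
  }
  cc_delta[reference, ]
}

#' Full response table for a mutant profile against a wild-type baseline
#'
#' @param value Mutant per-position values.
#' @param base A `dcm_baseline` from the wild-type set.
#' @return Tibble with `position`, `value`, `z`, `delta_n`, `bin`,
#'   `zero_sigma`.
#' @export
response_table <- function(value, base) {
  z <- baseline_z(value, base)
  zs <- attr(z, "zero_sigma")
  tibble::tibble(
    position = seq_along(base$mean),
    value = as.vector(value),
    z = as.vector(z),
    delta_n = normalized_delta(as.vector(z)),
    bin = classify_bins(ifelse(is.infinite(z), sign(z) * 3, z)),
    zero_sigma = zs)
}
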