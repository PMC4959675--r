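#' Specification of a synthetic diel expression data set
#'
#' Defines the generative model for ground-truth-labelled expression series
#' on the canonical 48-h grid. A cyclic gene follows
#' \deqn{g(t) = \alpha t + \beta + (A/2)\cos(2\pi t/T - \phi) + \epsilon,}
#' with \eqn{\epsilon \sim N(0, \sigma^2)}; a non-cyclic gene omits the
#' cosine term. `A` is the peak-to-trough amplitude (the cosine coefficient
#' is `A/2`), matching the convention amplitude = 2*sqrt(a^2 + b^2) used by
#' the rhythm detector, so recovered and generating amplitudes compare
#' directly.
#'
#' Defaults emulate a diurnally entrained prokaryotic transcriptome profiled
#' on two-channel arrays: roughly 40% of genes cycling, peak-to-trough
#' amplitudes of 1--3 log2 units, mild linear drift and measurement noise of
#' 0.2 log2 units. True periods sit in a narrow band around 24 h because
#' entrainment by a 12:12 light/dark driver locks transcript rhythms to the
#' driver's period; wider dispersion would model free-running circadian
#' drift, not driven diurnal expression.
#'
#' @param n_genes Number of genes.
#' @param fraction_cyclic Fraction of genes carrying a cosine component.
#' @param period_range Range (h) of true periods, sampled uniformly.
#' @param amplitude_range Range (log2 units) of peak-to-trough amplitudes.
#' @param acrophase_range Range (radians) of acrophases.
#' @param trend_slope_range Range (log2 units / h) of linear trend slopes.
#' @param intercept_range Range (log2 units) of baseline offsets.
#' @param noise_sd Gaussian noise standard deviation (log2 units), >= 0.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#'
#' @return An object of class `"synthetic_spec"` (a validated list).
#' @seealso [generate_expression()]
#' @export
synthetic_spec <- function(n_genes = 1000L,
                           fraction_cyclic = 0.4,
                           period_range = c(23.5, 24.5),
                           amplitude_range = c(1, 3),
                           acrophase_range = c(0, 2 * pi),
                           trend_slope_range = c(-0.01, 0.01),
                           intercept_range = c(-0.5, 0.5),
                           noise_sd = 0.2,
                           seed = 1L) {
  .range_ok <- function(x, nm) {
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || any(!is.finite(x)) || x[2] < x[1])
      stop("invalid range for ", nm)
    x
  }
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 1)
    stop("n_genes must be a positive integer")
  if (fraction_cyclic < 0 || fraction_cyclic > 1)
    stop("fraction_cyclic must be in [0, 1]")
  if (length(noise_sd) != 1L || !is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be a finite non-negative number")
  spec <- list(
    n_genes = as.integer(n_genes),
    fraction_cyclic = fraction_cyclic,
    period_range = .range_ok(period_range, "period_range"),
    amplitude_range = .range_ok(amplitude_range, "amplitude_range"),
    acrophase_range = .range_ok(acrophase_range, "acrophase_range"),
    trend_slope_range = .range_ok(trend_slope_range, "trend_slope_range"),
    intercept_range = .range_ok(intercept_range, "intercept_range"),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  spec
}

.runif_range <- function(n, r) if (r[1] == r[2]) rep(r[1], n) else stats::runif(n, r[1], r[2])

#' Generate a ground-truth-labelled expression matrix
#'
#' Simulates log2-ratio expression series on the diel grid according to a
#' [synthetic_spec()]. The number of cyclic genes is `round(fraction_cyclic
#' * n_genes)`; which genes are cyclic is randomized under the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param grid A [diel_grid()] (the canonical 24-point grid).
#'
#' @return A list with
#'   \describe{
#'     \item{matrix}{numeric `n_genes` x 24 matrix of log2 ratios; row names
#'       are gene ids, column names `label_cycle` (e.g. `"D1_1"`). Carries
#'       attributes `scaled = FALSE` and the generating grid.}
#'     \item{truth}{data frame with one row per gene: `gene`, logical
#'       `cyclic`, and the generating `period`, `amplitude` (peak-to-trough),
#'       `acrophase`, `slope`, `intercept` (rhythm parameters are `NA` for
#'       non-cyclic genes).}
#'   }
#' @examples
#' sim <- generate_expression(synthetic_spec(n_genes = 50, seed = 7), diel_grid())
#' dim(sim$matrix)
#' table(sim$truth$cyclic)
#' @export
generate_expression <- function(spec, grid = diel_grid()) {
  if (!inherits(spec, "synthetic_spec")) stop("'spec' must be a synthetic_spec")
  .check_canonical_grid(grid)
  set.seed(spec$seed)
  n <- spec$n_genes
  t <- grid$time

  n_cyc <- as.integer(round(spec$fraction_cyclic * n))
  cyclic <- rep(FALSE, n)
  cyclic[sample.int(n, n_cyc)] <- TRUE

  period    <- ifelse(cyclic, .runif_range(n, spec$period_range), NA_real_)
  amplitude <- ifelse(cyclic, .runif_range(n, spec$amplitude_range), NA_real_)
  acrophase <- ifelse(cyclic, .runif_range(n, spec$acrophase_range), NA_real_)
  slope     <- .runif_range(n, spec$trend_slope_range)
  intercept <- .runif_range(n, spec$intercept_range)

  gene <- sprintf("g%04d", seq_len(n))
  mat <- matrix(NA_real_, n, length(t),
                dimnames = list(gene, paste0(grid$label, "_", grid$cycle)))
  for (i in seq_len(n)) {
    y <- slope[i] * t + intercept[i]
    if (cyclic[i])
      y <- y + (amplitude[i] / 2) * cos(2 * pi * t / period[i] - acrophase[i])
    mat[i, ] <- y
  }
  if (spec$noise_sd > 0)
    mat <- mat + matrix(stats::rnorm(length(mat), 0, spec$noise_sd), nrow = n)

  attr(mat, "scaled") <- FALSE
  attr(mat, "grid") <- grid
  truth <- data.frame(gene = gene, cyclic = cyclic, period = period,
                      amplitude = amplitude, acrophase = acrophase,
                      slope = slope, intercept = intercept,
                      stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth)
}

#' Emulate two-channel probe intensities for an expression matrix
#'
#' Turns a gene x timepoint log2-ratio matrix into a long table of raw
#' two-channel probe measurements so that the preprocessing stage
#' (background subtraction, LOWESS normalization, probe aggregation) can be
#' exercised against known truth. Each gene receives one or two probes; a
#' probe's mean log-intensity is a fixed probe property, and per array the
#' two channel foregrounds are chosen so that the background-corrected
#' log2(experiment/control) ratio equals the matrix value plus an injected
#' smooth intensity-dependent dye bias `dye_bias(A)` (where
#' A = 0.5*log2(exp*ctl)). Additive backgrounds are drawn per measurement.
#'
#' The table also carries `n_control` normalization-control probes whose
#' true log2 ratio is zero at every timepoint, spanning the intensity range
#' evenly; these play the role of the zero-ratio training spots used to
#' anchor intensity-dependent normalization on real two-channel arrays.
#'
#' @param mat Gene x 24 matrix (e.g. `generate_expression()$matrix`).
#' @param grid The [diel_grid()] the matrix columns follow.
#' @param seed Integer seed.
#' @param dye_bias Function of A returning the injected bias in log2 units
#'   (default: no bias).
#' @param bg_level Mean additive background intensity (0 = no background).
#' @param two_probe_fraction Fraction of genes measured by two probes.
#' @param n_control Number of zero-ratio control probes.
#' @param intensity_range Range of probe mean log2 intensities.
#'
#' @return A data frame of class `"probe_table"` with columns `probe`,
#'   `gene` (`NA` for control probes), `array` (column name of `mat`),
#'   `exp_fg`, `exp_bg`, `ctl_fg`, `ctl_bg`, `control`.
#' @export
generate_probe_intensities <- function(mat, grid = attr(mat, "grid"),
                                       seed = 1L,
                                       dye_bias = function(A) rep(0, length(A)),
                                       bg_level = 0,
                                       two_probe_fraction = 0.2,
                                       n_control = 100L,
                                       intensity_range = c(7, 14)) {
  if (!is.matrix(mat) || !all(is.finite(mat))) stop("'mat' must be a finite numeric matrix")
  .check_canonical_grid(grid)
  if (ncol(mat) != length(grid$time)) stop("matrix columns do not match the grid")
  set.seed(seed)

  genes <- rownames(mat)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(nrow(mat)))
  arrays <- colnames(mat)
  if (is.null(arrays)) arrays <- paste0(grid$label, "_", grid$cycle)

  two <- stats::runif(length(genes)) < two_probe_fraction
  probe_gene <- rep(genes, ifelse(two, 2L, 1L))
  probe_id <- paste0(probe_gene, "_p", unlist(lapply(ifelse(two, 2L, 1L), seq_len)))
  # probe intensity is a property of the spot, constant across arrays
  probe_A <- stats::runif(length(probe_id), intensity_range[1], intensity_range[2])

  if (n_control > 0) {
    ctrl_id <- sprintf("CTRL_%03d", seq_len(n_control))
    ctrl_A <- seq(intensity_range[1], intensity_range[2], length.out = n_control)
    probe_id <- c(probe_id, ctrl_id)
    probe_gene <- c(probe_gene, rep(NA_character_, n_control))
    probe_A <- c(probe_A, ctrl_A)
  }
  is_ctrl <- is.na(probe_gene)
  np <- length(probe_id)
  na <- length(arrays)

  idx <- match(probe_gene, genes)
  M_true <- matrix(0, np, na)
  M_true[!is_ctrl, ] <- mat[idx[!is_ctrl], , drop = FALSE]
  M_obs <- M_true + matrix(rep(dye_bias(probe_A), na), np, na)

  A <- matrix(rep(probe_A, na), np, na)
  exp_sig <- 2^(A + M_obs / 2)
  ctl_sig <- 2^(A - M_obs / 2)
  draw_bg <- function() {
    if (bg_level <= 0) matrix(0, np, na)
    else matrix(stats::runif(np * na, 0, 2 * bg_level), np, na)
  }
  exp_bg <- draw_bg(); ctl_bg <- draw_bg()

  out <- data.frame(
    probe = rep(probe_id, na),
    gene = rep(probe_gene, na),
    array = rep(arrays, each = np),
    exp_fg = as.vector(exp_sig + exp_bg),
    exp_bg = as.vector(exp_bg),
    ctl_fg = as.vector(ctl_sig + ctl_bg),
    ctl_bg = as.vector(ctl_bg),
    control = rep(is_ctrl, na),
    stringsAsFactors = FALSE
  )
  class(out) <- c("probe_table", "data.frame")
  out
}
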