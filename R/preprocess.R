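#' Background-subtract a two-channel probe table
#'
#' Per channel, corrected foreground = max(foreground - background, floor).
#' The floor keeps subsequent log-ratios defined when background exceeds
#' foreground (a weak or absent spot).
#'
#' @param table A probe table as produced by [generate_probe_intensities()]
#'   or read from TSV with the same columns.
#' @param floor Small positive clamp for corrected intensities.
#' @return The table with `exp_fg`/`ctl_fg` replaced by corrected
#'   intensities and both background columns set to zero.
#' @export
subtract_background <- function(table, floor = 1) {
  .check_probe_table(table)
  if (floor <= 0) stop("'floor' must be positive")
  if (any(table$exp_fg < 0) || any(table$ctl_fg < 0))
    stop("negative foreground intensities in input")
  table$exp_fg <- pmax(table$exp_fg - table$exp_bg, floor)
  table$ctl_fg <- pmax(table$ctl_fg - table$ctl_bg, floor)
  table$exp_bg <- 0
  table$ctl_bg <- 0
  table
}

.check_probe_table <- function(table) {
  need <- c("probe", "gene", "array", "exp_fg", "exp_bg", "ctl_fg", "ctl_bg")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("probe table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !is.finite(table$exp_fg) | !is.finite(table$ctl_fg)
  if (any(bad)) stop("non-finite intensities in probe table")
  invisible(table)
}

#' Intensity-dependent (LOWESS) normalization of probe log-ratios
#'
#' For each array independently: compute M = log2(exp/ctl) and
#' A = 0.5*log2(exp*ctl) from background-corrected intensities, fit a LOWESS
#' curve of M on A over the training probes with a smoothing window covering
#' `window_fraction` of the points, and subtract the fitted curve from every
#' probe's M, evaluating the curve between training points by linear
#' interpolation (constant extrapolation beyond the training range).
#'
#' The training set anchors the curve: with `training = "auto"` the
#' zero-ratio control probes are used when the table flags any
#' (`control == TRUE`), otherwise all probes of the array. `"all"` forces
#' the latter, which assumes most genes are unchanged relative to the
#' pooled control.
#'
#' @param table A background-corrected probe table (see
#'   [subtract_background()]).
#' @param window_fraction LOWESS smoother span in (0, 1].
#' @param training `"auto"`, `"control"` or `"all"`.
#' @return Data frame `probe`, `gene`, `array`, `A`, `ratio` (normalized
#'   log2 ratio), `control`.
#' @export
lowess_normalize <- function(table, window_fraction = 0.25,
                             training = c("auto", "control", "all")) {
  .check_probe_table(table)
  training <- match.arg(training)
  if (window_fraction <= 0 || window_fraction > 1)
    stop("'window_fraction' must be in (0, 1]")
  ef <- table$exp_fg - table$exp_bg
  cf <- table$ctl_fg - table$ctl_bg
  if (any(ef <= 0) || any(cf <= 0))
    stop("background-corrected intensities must be positive; run subtract_background() first")
  M <- log2(ef / cf)
  A <- 0.5 * log2(ef * cf)
  has_ctrl <- "control" %in% names(table) && any(table$control)
  use_ctrl <- switch(training,
                     auto = has_ctrl,
                     control = { if (!has_ctrl) stop("no control probes in table"); TRUE },
                     all = FALSE)

  out <- vector("list", 0L)
  for (arr in unique(table$array)) {
    sel <- table$array == arr
    tr <- if (use_ctrl) sel & table$control else sel
    n_tr <- sum(tr)
    if (n_tr < ceiling(1 / window_fraction))
      stop("array '", arr, "': only ", n_tr,
           " training probes; too few for window_fraction = ", window_fraction)
    fit <- stats::lowess(A[tr], M[tr], f = window_fraction)
    corr <- stats::approx(fit$x, fit$y, xout = A[sel], rule = 2, ties = mean)$y
    out[[length(out) + 1L]] <- data.frame(
      probe = table$probe[sel], gene = table$gene[sel], array = arr,
      A = A[sel], ratio = M[sel] - corr,
      control = if ("control" %in% names(table)) table$control[sel] else FALSE,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Average probe-level log2 ratios into a gene x timepoint matrix
#'
#' A gene's expression at a timepoint is the arithmetic mean of the
#' normalized log2 ratios of its probes on that array. Control probes
#' (`gene` = `NA`) are dropped.
#'
#' @param ratios Output of [lowess_normalize()] (columns `gene`, `array`,
#'   `ratio`), or any data frame with those columns.
#' @param grid The [diel_grid()]; its `label_cycle` column names define the
#'   timepoint order.
#' @return Numeric gene x 24 matrix with attributes `scaled = FALSE` and
#'   `grid`.
#' @export
aggregate_probes <- function(ratios, grid = diel_grid()) {
  .check_canonical_grid(grid)
  need <- c("gene", "array", "ratio")
  if (!all(need %in% names(ratios))) stop("ratios need columns gene/array/ratio")
  ratios <- ratios[!is.na(ratios$gene), , drop = FALSE]
  cols <- paste0(grid$label, "_", grid$cycle)
  if (!all(ratios$array %in% cols))
    stop("array label(s) not on the grid: ",
         paste(setdiff(unique(ratios$array), cols), collapse = ", "))
  genes <- sort(unique(ratios$gene))
  agg <- tapply(ratios$ratio,
                list(factor(ratios$gene, genes), factor(ratios$array, cols)),
                mean)
  if (anyNA(agg)) {
    bad <- which(is.na(agg), arr.ind = TRUE)
    stop("gene '", genes[bad[1, 1]], "' has no probe measurement at timepoint '",
         cols[bad[1, 2]], "'")
  }
  mat <- matrix(agg, nrow = length(genes), dimnames = list(genes, cols))
  attr(mat, "scaled") <- FALSE
  attr(mat, "grid") <- grid
  mat
}

#' Feature-scale expression profiles to [-1, +1]
#'
#' Per gene: scaled = 2*(g - min)/(max - min) - 1, so every non-constant
#' profile attains exactly -1 and +1 and all genes contribute equally to
#' rhythm detection and correlation, regardless of their raw dynamic range.
#' Constant profiles map to all zeros; they carry no rhythm information and
#' can never satisfy the cyclicity criteria.
#'
#' @param mat Gene x timepoint numeric matrix.
#' @return The scaled matrix with attribute `scaled = TRUE` (grid attribute
#'   preserved).
#' @export
feature_scale <- function(mat) {
  if (!is.matrix(mat)) stop("'mat' must be a matrix")
  if (any(!is.finite(mat))) stop("non-finite values in expression matrix")
  rmin <- apply(mat, 1, min)
  rmax <- apply(mat, 1, max)
  rng <- rmax - rmin
  out <- mat
  const <- rng == 0
  if (any(!const))
    out[!const, ] <- 2 * (mat[!const, , drop = FALSE] - rmin[!const]) / rng[!const] - 1
  if (any(const)) out[const, ] <- 0
  attr(out, "scaled") <- TRUE
  attr(out, "grid") <- attr(mat, "grid")
  out
}

#' Is a matrix feature-scaled?
#' @param mat An expression matrix.
#' @return Logical flag stored by [feature_scale()] (FALSE if absent).
#' @export
is_feature_scaled <- function(mat) isTRUE(attr(mat, "scaled"))
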