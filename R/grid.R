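#' The canonical 48-h diel sampling grid
#'
#' Two consecutive 12-h light / 12-h dark cycles sampled every 2 h starting
#' 1 h into the first dark period: 24 samples at t = 1, 3, ..., 47 h.
#' Sample labels give the hour within the current dark ("D1"..."D11") or
#' light ("L1"..."L11") phase and repeat identically across the two cycles.
#'
#' @param n_cycles Number of 24-h cycles (the canonical design uses 2).
#'
#' @return An object of class `"diel_grid"`: a list with
#'   \describe{
#'     \item{time}{numeric hours since the start of the first dark period}
#'     \item{label}{phase-hour label of each sample ("D1", ..., "L11")}
#'     \item{cycle}{cycle index (1 or 2) of each sample}
#'     \item{phase}{"dark" or "light" for each sample}
#'     \item{label_levels}{the 12 distinct labels in within-cycle order
#'       (D1, D3, ..., D11, L1, ..., L11)}
#'     \item{label_hours}{clock hour (position in the 24-h cycle) of each
#'       distinct label}
#'   }
#' @examples
#' g <- diel_grid()
#' g$time        # 1 3 5 ... 47
#' g$label[1:3]  # "D1" "D3" "D5"
#' @export
diel_grid <- function(n_cycles = 2L) {
  stopifnot(n_cycles >= 1L)
  hour_in_cycle <- seq(1, 23, by = 2)
  lab <- ifelse(hour_in_cycle < 12,
                paste0("D", hour_in_cycle),
                paste0("L", hour_in_cycle - 12))
  grid <- list(
    time  = as.numeric(rep(hour_in_cycle, n_cycles) + 24 * rep(seq_len(n_cycles) - 1L, each = 12L)),
    label = rep(lab, n_cycles),
    cycle = rep(seq_len(n_cycles), each = 12L),
    phase = rep(ifelse(hour_in_cycle < 12, "dark", "light"), n_cycles),
    label_levels = lab,
    label_hours  = hour_in_cycle
  )
  class(grid) <- "diel_grid"
  grid
}

#' @export
print.diel_grid <- function(x, ...) {
  cat("diel sampling grid: ", length(x$time), " samples, t = ",
      x$time[1], "..", x$time[length(x$time)], " h, ",
      max(x$cycle), " cycle(s)\n", sep = "")
  invisible(x)
}

#' @export
length.diel_grid <- function(x) length(x$time)

#' Light/dark phase of a sample label
#'
#' @param label Character vector of labels such as "D1" or "L11".
#' @return `"light"` for L-labels, `"dark"` for D-labels.
#' @export
label_phase <- function(label) {
  out <- ifelse(startsWith(label, "L"), "light",
                ifelse(startsWith(label, "D"), "dark", NA_character_))
  if (anyNA(out)) stop("unrecognized phase label(s): ",
                       paste(unique(label[is.na(out)]), collapse = ", "))
  out
}

.check_canonical_grid <- function(grid) {
  if (!inherits(grid, "diel_grid")) stop("'grid' must be a diel_grid object")
  if (length(grid$time) != 24L)
    stop("the canonical grid has 24 samples; got ", length(grid$time))
  invisible(grid)
}
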