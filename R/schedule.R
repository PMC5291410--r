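# Stage schedule (cleavage cycles, mitosis, division, time classes) and
# nucleus rows along the A-P axis.

#' Nucleus row
#'
#' A one-dimensional row of nuclei along the antero-posterior axis. Positions
#' are in % A-P (0% = anterior pole), strictly increasing and equally spaced
#' within a cycle; the spacing halves at each division.
#'
#' @param positions numeric vector of % A-P positions.
#' @param cycle_index cleavage-cycle index (number of preceding divisions).
#' @return an object of class `nucleus_row`.
#' @export
nucleus_row <- function(positions, cycle_index) {
  positions <- as.numeric(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (length(positions) > 2) {
    d <- diff(positions)
    if (max(abs(d - d[1])) > 1e-9 * d[1])
      stop("positions must be equally spaced within a cycle")
  }
  structure(list(positions = positions, n_nuclei = length(positions),
                 cycle_index = as.integer(cycle_index),
                 spacing = if (length(positions) > 1) diff(positions)[1] else NA_real_),
            class = "nucleus_row")
}

#' Default nucleus rows for the trunk region
#'
#' 29 nuclei at 2% spacing during cycle C13 (positions 35, 37, ..., 91) and
#' 58 nuclei at 1% spacing during C14A (35, 36, ..., 92), covering the trunk
#' between 35 and 92% A-P position.
#'
#' @return list with elements `C13` and `C14A`, each a `nucleus_row`.
#' @export
default_rows <- function() {
  list(C13  = nucleus_row(seq(35, 91, by = 2), 13L),
       C14A = nucleus_row(seq(35, 92, by = 1), 14L))
}

#' Nuclear division
#'
#' Doubles the nucleus count at the scheduled division instant. Each daughter
#' inherits its parent's concentration vector unchanged; positions are
#' re-spaced at half the previous spacing within the same spatial extent, and
#' the cycle index is incremented.
#'
#' @param state nuclei x genes concentration matrix on `row`.
#' @param row the pre-division `nucleus_row`.
#' @return list with elements `state` (2n x genes) and `row` (the daughter
#'   row).
#' @export
divide_nuclei <- function(state, row) {
  state <- as.matrix(state)
  if (nrow(state) != row$n_nuclei)
    stop("state does not match the nucleus row")
  half <- row$spacing / 2
  new_pos <- as.vector(rbind(row$positions, row$positions + half))
  idx <- rep(seq_len(row$n_nuclei), each = 2L)
  list(state = state[idx, , drop = FALSE],
       row = nucleus_row(new_pos, row$cycle_index + 1L))
}

#' Stage schedule
#'
#' The hybrid simulation timeline: a C13 interphase, a C13 mitosis with
#' production switched off, an instantaneous nuclear division, and cleavage
#' cycle 14A partitioned into eight equal time classes (T1-T8), ending at the
#' onset of gastrulation. The ten phase-portrait analysis times are C13
#' (mid-interphase), the midpoints of T1-T8, and gastrulation time.
#'
#' @param t_interphase13 duration of the C13 interphase (min).
#' @param t_mitosis13 duration of the C13 mitotic phase (min).
#' @param t_c14 duration of cycle C14A (min), split into `n_classes` classes.
#' @param n_classes number of equal C14A time classes.
#' @return an object of class `stage_schedule` with the phase table, the
#'   division time, time-class boundaries and the named `analysis_times`.
#' @export
stage_schedule <- function(t_interphase13 = 16, t_mitosis13 = 4,
                           t_c14 = 50, n_classes = 8L) {
  t_div <- t_interphase13 + t_mitosis13
  t_end <- t_div + t_c14
  class_bounds <- seq(t_div, t_end, length.out = n_classes + 1L)
  phases <- data.frame(
    name = c("C13-interphase", "C13-mitosis",
             paste0("C14A-T", seq_len(n_classes))),
    start = c(0, t_interphase13, class_bounds[-(n_classes + 1L)]),
    end = c(t_interphase13, t_div, class_bounds[-1L]),
    production = c(TRUE, FALSE, rep(TRUE, n_classes)),
    cycle = c(13L, 13L, rep(14L, n_classes)),
    stringsAsFactors = FALSE)
  mid <- (class_bounds[-1L] + class_bounds[-(n_classes + 1L)]) / 2
  analysis_times <- c(t_interphase13 / 2, mid, t_end)
  names(analysis_times) <- c("C13", paste0("T", seq_len(n_classes)), "gast")
  structure(list(phases = phases, division_time = t_div, t_end = t_end,
                 class_bounds = class_bounds,
                 analysis_times = analysis_times),
            class = "stage_schedule")
}

#' Time-class label of a time point
#'
#' @param t time in minutes.
#' @param schedule a `stage_schedule`.
#' @return character label ("C13", "T1", ..., "T8", "gast").
#' @export
time_class_label <- function(t, schedule) {
  vapply(t, function(tt) {
    if (tt >= schedule$t_end) return("gast")
    if (tt < schedule$division_time) return("C13")
    k <- findInterval(tt, schedule$class_bounds, rightmost.closed = TRUE)
    paste0("T", min(k, length(schedule$class_bounds) - 1L))
  }, character(1))
}

#' Resolve a time label to minutes
#'
#' Maps analysis-time labels ("C13", "T1".."T8", "gast") to the corresponding
#' analysis times; numeric input is passed through.
#'
#' @param x character labels or numeric minutes.
#' @param schedule a `stage_schedule`.
#' @return numeric minutes.
#' @export
resolve_time <- function(x, schedule) {
  if (is.numeric(x)) return(x)
  at <- schedule$analysis_times
  bad <- !(x %in% names(at))
  if (any(bad)) stop("unknown time label(s): ", paste(x[bad], collapse = ", "))
  unname(at[x])
}
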