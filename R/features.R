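# Expression-pattern features: half-maximum domain boundaries, boundary
# time courses, shift rates, and frozen-vs-dynamic overshoot.

#' Extract expression domains from a spatial profile
#'
#' Domains are contiguous runs of nuclei whose concentration exceeds the
#' threshold (by default half of the profile's own maximum, which makes the
#' extraction invariant under uniform rescaling). Boundary positions are
#' interpolated linearly between the two nuclei flanking each threshold
#' crossing; a run touching the edge of the modelled range uses the edge
#' position. Domains spanning fewer than `min_width` nuclei are discarded as
#' noise speckles.
#'
#' @param positions numeric vector of % A-P positions (>= 3 nuclei).
#' @param concentration matching concentrations of one gene at one time.
#' @param threshold absolute threshold (au); default `max(concentration)/2`.
#' @param min_width minimum run length in nuclei (default 2).
#' @return data frame with columns `anterior`, `posterior` (interpolated
#'   boundary positions, % A-P) and `peak` (au), ordered anterior to
#'   posterior; zero rows for an all-zero profile.
#' @export
extract_domains <- function(positions, concentration, threshold = NULL,
                            min_width = 2L) {
  n <- length(positions)
  stopifnot(n == length(concentration), n >= 3)
  if (all(concentration <= 0))
    return(data.frame(anterior = numeric(0), posterior = numeric(0),
                      peak = numeric(0)))
  if (is.null(threshold)) threshold <- max(concentration) / 2
  above <- concentration >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  cross <- function(i0, i1) {
    # linear interpolation of the threshold crossing between nuclei i0, i1
    c0 <- concentration[i0]; c1 <- concentration[i1]
    positions[i0] + (threshold - c0) / (c1 - c0) *
      (positions[i1] - positions[i0])
  }
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_width) next
    i_a <- starts[k]; i_p <- ends[k]
    ant <- if (i_a == 1L) positions[1L] else cross(i_a - 1L, i_a)
    post <- if (i_p == n) positions[n] else cross(i_p, i_p + 1L)
    out[[length(out) + 1L]] <- data.frame(
      anterior = ant, posterior = post,
      peak = max(concentration[i_a:i_p]))
  }
  if (length(out) == 0)
    return(data.frame(anterior = numeric(0), posterior = numeric(0),
                      peak = numeric(0)))
  do.call(rbind, out)
}

#' Boundary time course of a gene
#'
#' Extracts half-maximum domains at each analysis time and links boundaries
#' across times by nearest position (relative to the previous time's linked
#' boundary). Times where a linked domain is missing produce gaps, not
#' errors.
#'
#' @param traj a `circuit_trajectory` (or a tidy data frame with columns
#'   `time_min`, `position_pct`, `species`, `concentration`).
#' @param gene gene name.
#' @param side `"anterior"` or `"posterior"` boundary.
#' @param times analysis times (default: the trajectory schedule's).
#' @param max_jump maximum linking distance between consecutive times
#'   (% A-P).
#' @param ... passed to [extract_domains()].
#' @return data frame with columns `time`, `position`, `domain` (integer id
#'   linking the same domain across times).
#' @export
boundary_timecourse <- function(traj, gene, side = c("posterior", "anterior"),
                                times = NULL, max_jump = 15, ...) {
  side <- match.arg(side)
  df <- if (is.data.frame(traj)) traj else {
    if (is.null(times)) times <- traj$schedule$analysis_times
    as.data.frame(traj, times = times)
  }
  df <- df[df$species == gene, , drop = FALSE]
  if (is.null(times)) times <- sort(unique(df$time_min))
  prev <- NULL  # positions of the tracked boundaries, by domain id
  next_dom <- 0L
  rows <- list()
  for (t in times) {
    sl <- df[abs(df$time_min - t) < 1e-9, , drop = FALSE]
    sl <- sl[order(sl$position_pct), ]
    doms <- extract_domains(sl$position_pct, sl$concentration, ...)
    if (nrow(doms) == 0) { prev <- NULL; next }
    bpos <- doms[[side]]
    ids <- rep(NA_integer_, length(bpos))
    if (!is.null(prev) && nrow(prev) > 0) {
      for (j in order(bpos)) {
        d <- abs(prev$position - bpos[j])
        d[prev$taken] <- Inf
        if (length(d) > 0 && min(d) <= max_jump) {
          i <- which.min(d)
          ids[j] <- prev$domain[i]
          prev$taken[i] <- TRUE
        }
      }
    }
    new <- which(is.na(ids))
    ids[new] <- next_dom + seq_along(new)
    next_dom <- next_dom + length(new)
    prev <- data.frame(domain = ids, position = bpos, taken = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(time = t, position = bpos,
                                            domain = ids)
  }
  if (length(rows) == 0)
    return(data.frame(time = numeric(0), position = numeric(0),
                      domain = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$domain, out$time), , drop = FALSE]
}

#' Shift rate of a boundary time course
#'
#' Finite-difference rate per inter-class interval and the overall
#' least-squares slope. Negative rates are anterior-ward shifts.
#'
#' @param boundary data frame with columns `time` and `position` for one
#'   linked domain boundary.
#' @return list with `intervals` (data frame `t_from`, `t_to`, `rate` in
#'   % A-P per min), `slope` (overall least-squares slope), and `defined`
#'   (FALSE when fewer than 2 linked points are available).
#' @export
shift_rate <- function(boundary) {
  boundary <- boundary[order(boundary$time), , drop = FALSE]
  if (nrow(boundary) < 2)
    return(list(intervals = data.frame(t_from = numeric(0),
                                       t_to = numeric(0), rate = numeric(0)),
                slope = NA_real_, defined = FALSE))
  dt <- diff(boundary$time)
  dp <- diff(boundary$position)
  intervals <- data.frame(t_from = head(boundary$time, -1),
                          t_to = boundary$time[-1], rate = dp / dt)
  slope <- unname(coef(lm(position ~ time, data = boundary))[2])
  list(intervals = intervals, slope = slope, defined = TRUE)
}

#' Boundary overshoot of a frozen-gradient run
#'
#' Signed positional difference (frozen - dynamic) of matched boundaries per
#' time; negative values mean the frozen-run boundary lies anterior of the
#' dynamic one (the hallmark of unchecked posterior domain shifts when the
#' gradients do not decay).
#'
#' @param dynamic,frozen boundary time courses ([boundary_timecourse()]) of
#'   the same gene/side from the dynamic and frozen runs; the dominant
#'   (highest-peak, longest-lived) domain of each is matched by default when
#'   both contain a single domain id, otherwise supply one domain each.
#' @return list with `table` (columns `time`, `dynamic`, `frozen`,
#'   `difference`) and `final` (the difference at the last matched time);
#'   unmatched times are reported as gaps (dropped rows).
#' @export
overshoot <- function(dynamic, frozen) {
  pick <- function(b) {
    if (nrow(b) == 0) return(b)
    keep <- names(which.max(table(b$domain)))
    b[b$domain == as.integer(keep), , drop = FALSE]
  }
  d <- pick(dynamic); f <- pick(frozen)
  m <- merge(d[, c("time", "position")], f[, c("time", "position")],
             by = "time", suffixes = c("_dyn", "_frz"))
  tab <- data.frame(time = m$time, dynamic = m$position_dyn,
                    frozen = m$position_frz,
                    difference = m$position_frz - m$position_dyn)
  list(table = tab,
       final = if (nrow(tab) > 0) tab$difference[which.max(tab$time)]
       else NA_real_)
}
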