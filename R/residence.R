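# Water residence-time kinetics at carbonyl-O sites: occupancy traces by
# water identity, sojourn extraction with a single-frame grace rule,
# histogramming and mono-exponential fitting.

#' Per-site, per-frame bound-water identities
#'
#' For every frame and site, records which water oxygens lie within
#' \code{cutoff} (minimum image when a box is present). Identity is the
#' water oxygen's topology row; water hydrogens are never consulted, so
#' libration cannot end an episode.
#'
#' @param traj an \code{hs_trajectory} containing water.
#' @param sites an \code{hs_sites} table.
#' @param cutoff Angstrom; 3.5 is the conventional single-frame site cutoff.
#' @return object of class \code{hs_trace}: \code{hits} data.frame
#'   (frame, site, water), plus \code{sites}, \code{n_frames},
#'   \code{frame_interval}, \code{cutoff_used}.
#' @export
occupancy_trace <- function(traj, sites, cutoff = 3.5) {
  wat <- water_oxygens(traj)
  if (!length(wat)) stop("no water oxygens in topology")
  nf <- n_frames(traj)
  out <- vector("list", nf)
  for (fi in seq_len(nf)) {
    d <- pair_distances(.site_coords(traj, sites, fi),
                        traj$frames[[fi]][wat, , drop = FALSE],
                        frame_box(traj, fi))
    hit <- which(d < cutoff, arr.ind = TRUE)
    if (nrow(hit))
      out[[fi]] <- data.frame(frame = fi, site = hit[, 1], water = wat[hit[, 2]])
  }
  hits <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(hits))
    hits <- data.frame(frame = integer(), site = integer(), water = integer())
  structure(list(hits = hits, sites = sites, n_frames = nf,
                 frame_interval = traj$frame_interval, cutoff_used = cutoff),
            class = "hs_trace")
}

#' @export
print.hs_trace <- function(x, ...) {
  cat(sprintf("<occupancy trace> %d sites x %d frames, cutoff %.2f A, %d bound water-frames\n",
              nrow(x$sites), x$n_frames, x$cutoff_used, nrow(x$hits)))
  invisible(x)
}

# Split sorted presence frames into sojourn runs: a gap of up to
# `grace` absent frames is bridged (the bridged frames count toward the
# duration); longer gaps end the sojourn at the last present frame.
.runs_from_frames <- function(f, grace) {
  gaps <- diff(f)
  brk <- which(gaps > grace + 1L)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(f))
  cbind(start = f[starts], end = f[ends])
}

#' Extract binding sojourns with the single-frame grace rule
#'
#' A sojourn is a maximal run of frames over which one water identity is
#' present at one site, where absences of up to \code{grace} consecutive
#' frames are bridged (the default, one frame, means a water that leaves
#' for a single time step and returns in the next has not ended its
#' episode; the rule is applied per gap, hence transitively across
#' alternating patterns). Duration is the bridged frame span times the
#' frame interval. Sojourns touching the first or last frame are flagged
#' censored.
#'
#' @param trace an \code{hs_trace}.
#' @param grace maximal bridged gap, frames (0 disables bridging).
#' @return data.frame of class \code{hs_sojourns}: site, role, water,
#'   start_frame, end_frame, duration_frames, duration_ps, censored; with
#'   attributes \code{frame_interval} and \code{n_frames}.
#' @export
sojourns <- function(trace, grace = 1L) {
  stopifnot(inherits(trace, "hs_trace"), grace >= 0)
  h <- trace$hits
  out <- list(); k <- 0L
  if (nrow(h)) {
    key <- paste(h$site, h$water)
    for (grp in split(seq_len(nrow(h)), key)) {
      f <- sort(h$frame[grp])
      runs <- .runs_from_frames(f, as.integer(grace))
      k <- k + 1L
      out[[k]] <- data.frame(site = h$site[grp[1]], water = h$water[grp[1]],
                             start_frame = runs[, "start"],
                             end_frame = runs[, "end"])
    }
  }
  s <- if (k) do.call(rbind, out) else
    data.frame(site = integer(), water = integer(),
               start_frame = integer(), end_frame = integer())
  s <- s[order(s$site, s$start_frame, s$water), , drop = FALSE]
  s$role <- trace$sites$role[s$site]
  s$duration_frames <- s$end_frame - s$start_frame + 1L
  s$duration_ps <- s$duration_frames * trace$frame_interval
  s$censored <- s$start_frame == 1L | s$end_frame == trace$n_frames
  rownames(s) <- NULL
  structure(s, frame_interval = trace$frame_interval,
            n_frames = trace$n_frames,
            class = c("hs_sojourns", "data.frame"))
}

.uncensored <- function(soj, include_censored = FALSE) {
  if (include_censored) soj$duration_ps else soj$duration_ps[!soj$censored]
}

#' Mean residence time
#'
#' Arithmetic mean of the (by default uncensored) sojourn durations.
#'
#' @param soj an \code{hs_sojourns} table (optionally pre-filtered by role).
#' @param include_censored include episodes truncated by the trajectory ends.
#' @return mean residence time, ps.
#' @export
mean_residence <- function(soj, include_censored = FALSE) {
  d <- .uncensored(soj, include_censored)
  if (!length(d)) stop("no (uncensored) sojourns to average")
  mean(d)
}

#' Residence-time histogram f(t)
#'
#' Bins the sojourn durations; the bin counts form the temporal correlation
#' function f(t) whose mono-exponential decay constant is the mean residence
#' time. Empty tail bins are trimmed.
#'
#' @param soj an \code{hs_sojourns} table.
#' @param bin_width ps; defaults to the frame interval.
#' @param include_censored include censored episodes.
#' @return object of class \code{hs_hist}: \code{breaks}, bin centres
#'   \code{t}, \code{counts}, \code{bin_width}.
#' @export
residence_histogram <- function(soj, bin_width = NULL,
                                include_censored = FALSE) {
  d <- .uncensored(soj, include_censored)
  if (!length(d)) stop("no (uncensored) sojourns to bin")
  if (is.null(bin_width)) bin_width <- attr(soj, "frame_interval")
  breaks <- seq(0, (ceiling(max(d) / bin_width)) * bin_width, by = bin_width)
  counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE,
                                  left.open = TRUE),
                     nbins = length(breaks) - 1L)
  last <- max(which(counts > 0))
  counts <- counts[seq_len(last)]
  breaks <- breaks[seq_len(last + 1L)]
  structure(list(breaks = breaks,
                 t = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, bin_width = bin_width),
            class = "hs_hist")
}

#' Mono-exponential fit of a residence histogram
#'
#' Nonlinear least squares of \eqn{f(t) = A e^{-t/\tau}} against the bin
#' centres and counts, zero-count bins excluded, started from a log-linear
#' regression. Returns the amplitude, the mean residence time and an
#' unweighted coefficient of determination.
#'
#' @param hist an \code{hs_hist} with at least 3 nonzero bins.
#' @return object of class \code{hs_expfit}: \code{A}, \code{tau_mean} (ps),
#'   \code{r_squared}, \code{bin_width}.
#' @export
fit_exponential <- function(hist) {
  keep <- hist$counts > 0
  if (sum(keep) < 3) stop("need at least 3 nonzero bins to fit")
  t <- hist$t[keep]; y <- hist$counts[keep]
  lf <- stats::lm(log(y) ~ t)
  tau0 <- unname(-1 / stats::coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t) / 2
  A0 <- unname(exp(stats::coef(lf)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau),
                      start = list(A = A0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- stats::coef(fit)
  } else {
    # non-exponential data (e.g. a flat histogram) can make the Jacobian
    # singular for the Levenberg-Marquardt path; fall back to direct SSE
    # minimisation so a poor fit is reported rather than an error
    sse <- function(par) sum((y - par[1] * exp(-t / exp(par[2])))^2)
    op <- tryCatch(stats::optim(c(A0, log(tau0)), sse),
                   error = function(e) stop("exponential fit failed: ",
                                            conditionMessage(e)))
    p <- c(A = op$par[1], tau = exp(op$par[2]))
  }
  resid <- y - p[["A"]] * exp(-t / p[["tau"]])
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  structure(list(A = unname(p[["A"]]), tau_mean = unname(p[["tau"]]),
                 r_squared = r2, bin_width = hist$bin_width),
            class = "hs_expfit")
}

#' @export
print.hs_expfit <- function(x, ...) {
  cat(sprintf("<exp fit> f(t) = %.4g * exp(-t / %.4g ps), R^2 = %.4f\n",
              x$A, x$tau_mean, x$r_squared))
  invisible(x)
}

#' Fraction of departures proceeding by substitution
#'
#' A departure is a sojourn end not censored by the trajectory end. It is
#' counted as a substitution when the site's occupant count in the following
#' frame has not dropped below the site's modal (most frequent) count —
#' i.e. the leaving water was immediately replaced. Reported per role; roles
#' with no departures are absent from the result.
#'
#' @param trace an \code{hs_trace}.
#' @param grace grace window passed to [sojourns()].
#' @return named numeric vector of substitution fractions per role.
#' @export
substitution_fraction <- function(trace, grace = 1L) {
  if (trace$n_frames < 2) stop("need at least two frames")
  soj <- sojourns(trace, grace = grace)
  dep <- soj[soj$end_frame < trace$n_frames, , drop = FALSE]
  if (!nrow(dep)) return(stats::setNames(numeric(0), character(0)))
  # per-site per-frame occupant counts
  cnt <- matrix(0L, nrow(trace$sites), trace$n_frames)
  if (nrow(trace$hits)) {
    tb <- table(factor(trace$hits$site, levels = seq_len(nrow(trace$sites))),
                factor(trace$hits$frame, levels = seq_len(trace$n_frames)))
    cnt <- matrix(as.integer(tb), nrow(trace$sites), trace$n_frames)
  }
  modal <- apply(cnt, 1, function(v) as.integer(names(which.max(table(v)))))
  ok <- cnt[cbind(dep$site, dep$end_frame + 1L)] >= modal[dep$site]
  c(tapply(ok, dep$role, mean))
}
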