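# Radial distribution functions and their running coordination integrals.

.min_box_width <- function(box) {
  # perpendicular widths of the cell: V / area of each face
  v <- abs(det(box))
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  areas <- c(sqrt(sum(cr(box[2, ], box[3, ])^2)),
             sqrt(sum(cr(box[1, ], box[3, ])^2)),
             sqrt(sum(cr(box[1, ], box[2, ])^2)))
  min(v / areas)
}

#' Radial distribution function g(r) with running integral n(r)
#'
#' Histogram of minimum-image centre-to-other distances, normalised per
#' spherical shell by the others' number density, averaged over frames and
#' centres. \code{n_cumulative} is the frame-averaged neighbour count within
#' each bin's upper edge per centre — the "indefinite radial integral" n(r)
#' whose value at the first g(r) minimum is the first-shell coordination
#' number.
#'
#' @param traj an \code{hs_trajectory} with a periodic box.
#' @param centers,others 1-based topology rows; identical indices appearing
#'   in both sets are excluded pairwise (no self pairs).
#' @param r_max largest binned radius, Angstrom; must not exceed half the
#'   smallest box width (minimum-image validity).
#' @param bin_width bin width, Angstrom.
#' @param frames frame indices to average over (default all).
#' @return object of class \code{hs_rdf}: \code{bin_edges}, bin centres
#'   \code{r}, \code{g}, \code{n_cumulative}, \code{reference_count},
#'   \code{density_used}.
#' @export
rdf <- function(traj, centers, others, r_max = 8, bin_width = 0.05,
                frames = NULL) {
  if (is.null(traj$boxes)) stop("rdf requires a periodic box for normalisation")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  edges <- seq(0, r_max, by = bin_width)
  if (abs(edges[length(edges)] - r_max) > 1e-9) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  rho_acc <- 0
  for (fi in frames) {
    box <- traj$boxes[[fi]]
    if (r_max > .min_box_width(box) / 2 + 1e-9)
      stop("r_max exceeds half the smallest box width: minimum image invalid")
    xyz <- traj$frames[[fi]]
    d <- pair_distances(xyz[centers, , drop = FALSE],
                        xyz[others, , drop = FALSE], box)
    self <- outer(centers, others, "==")
    d <- d[!self]
    d <- d[d <= r_max]
    counts <- counts + tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                                nbins = nb)
    rho_acc <- rho_acc + length(others) / abs(det(box))
  }
  nfr <- length(frames)
  rho <- rho_acc / nfr
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (nfr * length(centers) * shell_vol * rho)
  n_cum <- cumsum(counts) / (nfr * length(centers))
  structure(list(bin_edges = edges, r = (edges[-1] + edges[-length(edges)]) / 2,
                 g = g, n_cumulative = n_cum,
                 reference_count = length(centers), density_used = rho),
            class = "hs_rdf")
}

#' @export
print.hs_rdf <- function(x, ...) {
  cat(sprintf("<rdf> %d bins to %.2f A, %d centres, density %.5f A^-3\n",
              length(x$g), max(x$bin_edges), x$reference_count, x$density_used))
  invisible(x)
}

#' Coordination number n(r) at a cutoff
#'
#' Linear interpolation of the running integral at \code{r_cut}; at the
#' first minimum of g(r) this is the first-shell coordination number.
#'
#' @param profile an \code{hs_rdf}.
#' @param r_cut radius, Angstrom, within the binned range.
#' @return average neighbour count per centre.
#' @export
coordination_number <- function(profile, r_cut) {
  edges <- profile$bin_edges
  if (r_cut < 0 || r_cut > edges[length(edges)] + 1e-9)
    stop("r_cut outside the binned range")
  stats::approx(edges, c(0, profile$n_cumulative), xout = r_cut,
                rule = 1)$y
}

#' Locate the first two maxima and minima of g(r)
#'
#' Extrema are detected on a centred moving-average smoothing of g and
#' reported at bin centres, in alternating max/min order starting from the
#' first interior maximum. Missing extrema are returned as NA, not errors.
#'
#' @param profile an \code{hs_rdf} with at least 10 bins.
#' @param smoothing_window moving-average window, bins (odd; 1 = none).
#' @return list with \code{first_max}, \code{first_min}, \code{second_max},
#'   \code{second_min} (Angstrom or NA).
#' @export
find_extrema <- function(profile, smoothing_window = 5) {
  g <- profile$g; r <- profile$r
  if (length(g) < 10) stop("profile needs at least 10 bins")
  w <- max(1L, as.integer(smoothing_window))
  if (w %% 2L == 0L) w <- w + 1L
  gs <- if (w > 1) stats::filter(g, rep(1 / w, w), sides = 2) else g
  gs <- as.numeric(gs)
  ok <- which(!is.na(gs))
  out <- list(first_max = NA_real_, first_min = NA_real_,
              second_max = NA_real_, second_min = NA_real_)
  if (length(ok) < 3) return(out)
  seq_i <- ok[-c(1, length(ok))]
  is_max <- gs[seq_i] >= gs[seq_i - 1] & gs[seq_i] > gs[seq_i + 1]
  is_min <- gs[seq_i] <= gs[seq_i - 1] & gs[seq_i] < gs[seq_i + 1]
  want <- "max"; found <- list()
  for (j in seq_along(seq_i)) {
    if (want == "max" && is_max[j]) { found <- c(found, list(c("max", r[seq_i[j]]))); want <- "min" }
    else if (want == "min" && is_min[j]) { found <- c(found, list(c("min", r[seq_i[j]]))); want <- "max" }
    if (length(found) == 4) break
  }
  lab <- c("first_max", "first_min", "second_max", "second_min")
  for (j in seq_along(found)) out[[lab[j]]] <- as.numeric(found[[j]][2])
  out
}

#' Second-shell population by shell integration
#'
#' Difference of the running integral between the first and second minima
#' of g(r): all second-neighbour waters, hydrogen-bonded to the first shell
#' or not.
#'
#' @param profile an \code{hs_rdf}.
#' @param r_min1 first minimum, Angstrom (default 3.225).
#' @param r_min2 second minimum, Angstrom (default 5.61).
#' @return average second-shell neighbour count per centre.
#' @export
second_shell_integral <- function(profile, r_min1 = 3.225, r_min2 = 5.61) {
  if (r_min1 >= r_min2) stop("r_min1 must be below r_min2")
  coordination_number(profile, r_min2) - coordination_number(profile, r_min1)
}
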