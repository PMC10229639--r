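#' Nearest-neighbour distances of 2-D localizations
#'
#' Euclidean distance from each point to its closest other point, the basic
#' spacing statistic for motor surface densities measured by localization
#' microscopy. Coincident points yield distance 0 with a warning (repeated
#' localizations of one molecule are not collapsed).
#'
#' @param points data.frame or matrix with columns `x_nm`, `y_nm` (or two
#'   unnamed columns).
#' @return numeric vector of distances, one per point.
#' @export
nearest_neighbor_distances <- function(points) {
  pts <- as.data.frame(points)
  if (all(c("x_nm", "y_nm") %in% names(pts))) {
    x <- pts$x_nm; y <- pts$y_nm
  } else if (ncol(pts) >= 2) {
    x <- pts[[1]]; y <- pts[[2]]
  } else stop("points must have two coordinate columns")
  if (length(x) < 2) stop("need at least 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite")
  d <- nn_distances(as.numeric(x), as.numeric(y))
  if (any(d == 0)) warning("coincident points: zero nearest-neighbour distance")
  d
}

#' Centre of the nearest-neighbour distance distribution
#'
#' Histograms the distances (Freedman-Diaconis bins by default) and fits a
#' Gaussian by least squares, returning the fitted centre as the
#' characteristic spacing. If the fit fails the sample median is returned,
#' flagged.
#'
#' @param distances numeric vector from [nearest_neighbor_distances()].
#' @param bin_width histogram bin width, nm; `NULL` for Freedman-Diaconis.
#' @return list with `center` (nm), `sd`, `bin_width` and `fallback`
#'   (TRUE when the median fallback was used).
#' @export
fit_nn_center <- function(distances, bin_width = NULL) {
  if (length(distances) < 50)
    stop("need at least 50 distances for a stable histogram fit")
  if (is.null(bin_width)) {
    bin_width <- 2 * IQR(distances) / length(distances)^(1 / 3)
    if (bin_width <= 0) bin_width <- diff(range(distances)) / 30
    if (bin_width <= 0) bin_width <- 1
  }
  lo <- floor(min(distances) / bin_width) * bin_width
  breaks <- seq(lo, max(distances) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(distances, breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  df <- data.frame(mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                   count = counts)
  m0 <- mean(distances); s0 <- max(sd(distances), bin_width / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ a * exp(-(mid - mu)^2 / (2 * sigma^2)),
                      data = df,
                      start = list(a = max(df$count), mu = m0, sigma = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian fit failed; falling back to the sample median")
    return(list(center = median(distances), sd = sd(distances),
                bin_width = bin_width, fallback = TRUE))
  }
  cf <- coef(fit)
  list(center = unname(cf["mu"]), sd = abs(unname(cf["sigma"])),
       bin_width = bin_width, fallback = FALSE)
}

#' Filament length within motor reach of a pedestal bead
#'
#' With the actin filament touching the surface of a spherical pedestal
#' bead of radius R, the portion of the filament within a motor head's
#' reach h of the bead surface is the chord of the circle at sagitta h:
#' 2 sqrt(2 R h - h^2).
#'
#' @param bead_radius_nm pedestal bead radius R, nm.
#' @param reach_nm motor reach h (head height), nm; must be < R.
#' @return accessible filament length, nm.
#' @examples
#' accessible_length(1500, 20) # 488.26
#' @export
accessible_length <- function(bead_radius_nm = 1500, reach_nm = 20) {
  if (reach_nm <= 0 || bead_radius_nm <= 0)
    stop("radius and reach must be positive")
  if (reach_nm >= bead_radius_nm)
    stop("reach must be smaller than the bead radius")
  2 * sqrt(2 * bead_radius_nm * reach_nm - reach_nm^2)
}

#' Estimate heads within reach of the filament
#'
#' Combines the nearest-neighbour spacing of surface motors with the
#' accessible filament length: the 1-D estimate divides the chord length by
#' the spacing (matching the "length of filament available" framing); a 2-D
#' estimate treating the spacing as the scale of a square lattice
#' (density 1/spacing^2 over the chord x reach strip) is reported alongside.
#'
#' @param nn_center_nm characteristic motor spacing, nm.
#' @param bead_radius_nm pedestal bead radius, nm.
#' @param reach_nm motor reach, nm.
#' @return list with `accessible_length_nm`, `heads_in_reach` (1-D
#'   estimate) and `heads_in_reach_2d`.
#' @examples
#' heads_in_reach(119)$heads_in_reach # about 4.1
#' @export
heads_in_reach <- function(nn_center_nm, bead_radius_nm = 1500,
                           reach_nm = 20) {
  if (nn_center_nm <= 0) stop("spacing must be positive")
  len <- accessible_length(bead_radius_nm, reach_nm)
  list(accessible_length_nm = len,
       heads_in_reach = len / nn_center_nm,
       heads_in_reach_2d = len * 2 * reach_nm / nn_center_nm^2)
}

#' Read 2-D localization coordinates
#'
#' CSV with columns `x_nm,y_nm`.
#'
#' @param path file path.
#' @return data.frame with `x_nm`, `y_nm`.
#' @export
read_localizations <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  if (!all(c("x_nm", "y_nm") %in% names(df)))
    stop("localization file must have columns x_nm,y_nm")
  df
}
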