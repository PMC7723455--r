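#' Chemical-shift windows mapping Calpha shifts to secondary structure
#'
#' Per-residue ppm windows assigning Calpha chemical shift to helix, coil or
#' beta-sheet (aggregate) classes. The shipped defaults are the analysis
#' windows for the three labeled residue types:
#' \itemize{
#'   \item Met: helix 55.0-59.2 ppm, coil 52.7-54.8 ppm, sheet < 52.7 ppm
#'   \item Arg: helix 56.7-60.2 ppm, coil 54.0-56.6 ppm, sheet < 53.3 ppm
#'   \item His: helix 56-58.8 ppm, coil 52.5-56 ppm, sheet < 52.5 ppm
#' }
#' Windows are matched in descending-ppm order with closed boundaries, so a
#' shift exactly on a boundary shared by two windows belongs to the
#' higher-ppm window. Gaps between windows (e.g. Arg 53.3-54.0 ppm, whose
#' class the source windows leave undefined) classify as `"unassigned"` and
#' are never silently merged into a neighbor.
#'
#' @param windows optional named list overriding or extending the defaults:
#'   `list(Met = list(helix = c(55.0, 59.2), coil = c(52.7, 54.8),
#'   sheet = c(-Inf, 52.7)), ...)`; sheet windows are open-ended below
#' @return object of class `region_table`
#' @export
region_table <- function(windows = NULL) {
  def <- list(
    Met = list(helix = c(55.0, 59.2), coil = c(52.7, 54.8), sheet = c(-Inf, 52.7)),
    Arg = list(helix = c(56.7, 60.2), coil = c(54.0, 56.6), sheet = c(-Inf, 53.3)),
    His = list(helix = c(56.0, 58.8), coil = c(52.5, 56.0), sheet = c(-Inf, 52.5))
  )
  if (!is.null(windows)) def[names(windows)] <- windows
  for (res in names(def)) {
    w <- def[[res]]
    for (cl in names(w)) {
      if (length(w[[cl]]) != 2 || w[[cl]][1] >= w[[cl]][2]) {
        stop(sprintf("window %s/%s must be c(lo, hi) with lo < hi", res, cl),
             call. = FALSE)
      }
    }
  }
  structure(list(windows = def), class = "region_table")
}

#' Classify a Calpha chemical shift into a secondary-structure class
#'
#' @param residue residue type present in the table (e.g. "Met")
#' @param ca_ppm Calpha chemical shift (ppm); vectorized
#' @param table a [region_table()]
#' @return character vector in \{"helix", "coil", "sheet", "unassigned"\}
#' @examples
#' classify_shift("Met", c(57.0, 52.0, 54.9))
#' @export
classify_shift <- function(residue, ca_ppm, table = region_table()) {
  stopifnot(inherits(table, "region_table"))
  if (!residue %in% names(table$windows)) {
    stop(sprintf("unknown residue '%s'", residue), call. = FALSE)
  }
  w <- table$windows[[residue]]
  # descending ppm order; first closed-interval match wins
  ord <- order(vapply(w, function(v) v[2], numeric(1)), decreasing = TRUE)
  vapply(ca_ppm, function(x) {
    for (cl in names(w)[ord]) {
      if (x >= w[[cl]][1] && x <= w[[cl]][2]) return(cl)
    }
    "unassigned"
  }, character(1))
}

#' Random-coil reference chemical shifts
#'
#' Calpha/Cbeta random-coil shifts used as the zero point of the secondary
#' chemical shift. Defaults are read from the compilation shipped in
#' `inst/extdata/random_coil_shifts.csv` (standard published random-coil
#' values; the file is plain CSV and editable, since compilations differ at
#' the few-tenths-ppm level).
#'
#' @param path CSV with columns `residue`, `ca_ppm`, `cb_ppm`
#' @return object of class `random_coil_table` (named list residue ->
#'   c(ca, cb))
#' @export
random_coil_table <- function(path = system.file("extdata",
                                                 "random_coil_shifts.csv",
                                                 package = "dipshiftr")) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "ca_ppm", "cb_ppm") %in% names(df)))
  if (any(df$ca_ppm <= 0 | df$cb_ppm <= 0)) {
    stop("random-coil shifts must be positive ppm values", call. = FALSE)
  }
  tab <- stats::setNames(
    lapply(seq_len(nrow(df)), function(i) c(ca = df$ca_ppm[i], cb = df$cb_ppm[i])),
    df$residue
  )
  structure(tab, class = "random_coil_table")
}

#' Classify by the Calpha-Cbeta secondary chemical shift difference
#'
#' Computes \eqn{\Delta = (\delta_{C\alpha} - \delta_{C\alpha}^{rc}) -
#' (\delta_{C\beta} - \delta_{C\beta}^{rc})}, the difference of the secondary
#' shifts of Calpha and Cbeta, whose sign discriminates helix (positive) from
#' sheet (negative). Thresholds default to +/- 1.4 ppm and are explicit
#' configuration, not hidden constants.
#'
#' @param residue residue type present in `rc`
#' @param ca_ppm,cb_ppm observed shifts (ppm)
#' @param rc a [random_coil_table()]
#' @param t_helix,t_sheet positive thresholds (ppm) on Delta
#' @return "helix", "coil" or "sheet"
#' @export
classify_dca_dcb <- function(residue, ca_ppm, cb_ppm,
                             rc = random_coil_table(),
                             t_helix = 1.4, t_sheet = 1.4) {
  if (!residue %in% names(rc)) {
    stop(sprintf("no random-coil reference for residue '%s'", residue),
         call. = FALSE)
  }
  ref <- rc[[residue]]
  delta <- (ca_ppm - ref[["ca"]]) - (cb_ppm - ref[["cb"]])
  ifelse(delta > t_helix, "helix", ifelse(delta < -t_sheet, "sheet", "coil"))
}

#' 1D NMR spectrum
#'
#' @param ppm chemical-shift axis, strictly monotone; stored descending (NMR
#'   display convention) — ascending input is reversed and the original order
#'   recorded
#' @param intensity intensities, same length, finite
#' @return object of class `spectrum_1d`
#' @export
spectrum_1d <- function(ppm, intensity) {
  stopifnot(length(ppm) == length(intensity), all(is.finite(intensity)))
  d <- diff(ppm)
  if (all(d > 0)) {
    ord <- "ascending"; ppm <- rev(ppm); intensity <- rev(intensity)
  } else if (all(d < 0)) {
    ord <- "descending"
  } else stop("'ppm' axis must be strictly monotone", call. = FALSE)
  structure(list(ppm = ppm, intensity = intensity, input_order = ord),
            class = "spectrum_1d")
}

#' 2D NMR spectrum
#'
#' @param ppm_f1,ppm_f2 monotone axes; stored descending as in [spectrum_1d()]
#' @param intensity matrix of dimension (length f1, length f2), finite
#' @return object of class `spectrum_2d`
#' @export
spectrum_2d <- function(ppm_f1, ppm_f2, intensity) {
  stopifnot(is.matrix(intensity), nrow(intensity) == length(ppm_f1),
            ncol(intensity) == length(ppm_f2), all(is.finite(intensity)))
  fix <- function(ppm) {
    d <- diff(ppm)
    if (all(d > 0)) list(ppm = rev(ppm), rev = TRUE)
    else if (all(d < 0)) list(ppm = ppm, rev = FALSE)
    else stop("ppm axes must be strictly monotone", call. = FALSE)
  }
  a1 <- fix(ppm_f1); a2 <- fix(ppm_f2)
  if (a1$rev) intensity <- intensity[rev(seq_len(nrow(intensity))), , drop = FALSE]
  if (a2$rev) intensity <- intensity[, rev(seq_len(ncol(intensity))), drop = FALSE]
  structure(list(ppm_f1 = a1$ppm, ppm_f2 = a2$ppm, intensity = intensity),
            class = "spectrum_2d")
}

# trapezoid integral of a spectrum slice over [lo, hi] on a descending axis,
# with the window endpoints added by linear interpolation
.trapz_window <- function(ppm, intensity, lo, hi) {
  asc_ppm <- rev(ppm); asc_int <- rev(intensity)
  lo <- max(lo, asc_ppm[1]); hi <- min(hi, asc_ppm[length(asc_ppm)])
  if (hi <= lo) stop("integration window does not overlap the axis",
                     call. = FALSE)
  inside <- asc_ppm > lo & asc_ppm < hi
  xs <- c(lo, asc_ppm[inside], hi)
  ys <- stats::approx(asc_ppm, asc_int, xout = xs, rule = 2)$y
  pracma::trapz(xs, ys)
}

#' Integrate a 1D spectral region
#'
#' Trapezoidal area of the spectrum over a ppm window, orientation-corrected
#' so that the area of a positive peak is positive regardless of axis
#' direction. Units: intensity x ppm.
#'
#' @param spec a [spectrum_1d()]
#' @param window `c(lo, hi)` in ppm, overlapping the axis range
#' @return area
#' @export
integrate_region_1d <- function(spec, window) {
  stopifnot(inherits(spec, "spectrum_1d"), length(window) == 2)
  .trapz_window(spec$ppm, spec$intensity, min(window), max(window))
}

#' Integrate 2D crosspeak volumes over rectangular boxes
#'
#' Double-trapezoid volume of each box. Boxes must be pairwise disjoint:
#' overlapping boxes would double-count intensity and are rejected.
#'
#' @param spec a [spectrum_2d()]
#' @param boxes list of boxes, each `list(f1 = c(lo, hi), f2 = c(lo, hi))` in
#'   ppm
#' @return numeric vector of volumes (named after the boxes when the list is
#'   named)
#' @export
integrate_crosspeaks_2d <- function(spec, boxes) {
  stopifnot(inherits(spec, "spectrum_2d"), length(boxes) >= 1)
  norm <- lapply(boxes, function(b) {
    list(f1 = sort(b$f1), f2 = sort(b$f2))
  })
  if (length(norm) > 1) {
    for (i in seq_along(norm)) for (j in seq_len(i - 1)) {
      a <- norm[[i]]; b <- norm[[j]]
      if (a$f1[1] < b$f1[2] && b$f1[1] < a$f1[2] &&
          a$f2[1] < b$f2[2] && b$f2[1] < a$f2[2]) {
        stop(sprintf("boxes %d and %d overlap (double counting)", j, i),
             call. = FALSE)
      }
    }
  }
  vols <- vapply(norm, function(b) {
    # integrate along f2 for every f1 row, then along f1
    row_int <- vapply(seq_along(spec$ppm_f1), function(i) {
      .trapz_window(spec$ppm_f2, spec$intensity[i, ], b$f2[1], b$f2[2])
    }, numeric(1))
    .trapz_window(spec$ppm_f1, row_int, b$f1[1], b$f1[2])
  }, numeric(1))
  names(vols) <- names(boxes)
  vols
}

#' Class fractions from integrated areas or volumes
#'
#' Normalizes non-negative per-class areas/volumes to fractions summing to 1.
#'
#' @param x named non-negative numeric vector keyed by class
#' @return named fractions summing to 1
#' @examples
#' class_fractions(c(helix = 77, sheet = 23))
#' @export
class_fractions <- function(x) {
  if (any(x < 0)) stop("areas must be non-negative", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("all-zero input: no intensity to apportion", call. = FALSE)
  x / s
}
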