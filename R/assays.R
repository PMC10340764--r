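# Deterministic wet-assay arithmetic: plate-based DPP-IV inhibition, biuret
# peptide quantitation, ANS surface hydrophobicity, prolamin extraction rate.

#' Percent DPP-IV inhibition from plate absorbances
#'
#' \deqn{inhibition = 100 \times \left(1 - \frac{A_s - A_{sb}}{A_c - A_{cb}}\right)}
#' where \code{a_s}/\code{a_sb} are the sample and sample-blank absorbances
#' and \code{a_c}/\code{a_cb} the control and control-blank. Negative values
#' (apparent activation) are returned as-is with a warning, never clamped.
#' The result is invariant to adding a constant to all four readings and to
#' scaling all four by a non-zero factor.
#'
#' @param a_s,a_sb,a_c,a_cb Absorbances. Alternatively pass a list with these
#'   names as \code{a_s} (e.g. from [gen_plate()]).
#' @return Percent inhibition.
#' @examples
#' dppiv_inhibition(0.5, 0.1, 0.9, 0.1)  # 50
#' @export
dppiv_inhibition <- function(a_s, a_sb = NULL, a_c = NULL, a_cb = NULL) {
  if (is.list(a_s)) {
    r <- a_s
    a_s <- r$a_s; a_sb <- r$a_sb; a_c <- r$a_c; a_cb <- r$a_cb
  }
  vals <- c(a_s, a_sb, a_c, a_cb)
  if (length(vals) != 4L || any(!is.finite(vals)))
    stop("four finite absorbances (a_s, a_sb, a_c, a_cb) are required")
  if (a_c == a_cb) stop("control window a_c - a_cb is zero; assay not computable")
  out <- 100 * (1 - (a_s - a_sb) / (a_c - a_cb))
  if (out < 0) warning("negative inhibition (apparent activation): ",
                       format(out, digits = 4))
  out
}

#' Average plate readings per role, then compute inhibition
#'
#' Reads a plate CSV with columns \code{role} (one of \code{sample},
#' \code{sample_blank}, \code{control}, \code{control_blank}) and
#' \code{absorbance}; replicate wells are averaged per role before the
#' inhibition arithmetic.
#'
#' @param path Plate CSV path.
#' @return Percent inhibition.
#' @export
plate_inhibition <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("role", "absorbance") %in% names(tab)))
    stop("plate CSV must have 'role' and 'absorbance' columns")
  roles <- c("sample", "sample_blank", "control", "control_blank")
  if (!all(roles %in% tab$role))
    stop("plate CSV missing role(s): ",
         paste(setdiff(roles, tab$role), collapse = ", "))
  m <- vapply(roles, function(r) mean(tab$absorbance[tab$role == r]), 0)
  dppiv_inhibition(m[["sample"]], m[["sample_blank"]], m[["control"]],
                   m[["control_blank"]])
}

#' Biuret standard curve
#'
#' @param slope Absorbance per (mg/mL); must be non-zero. Default is the
#'   biuret calibration used throughout the package (y = 0.0721 x + 0.069).
#' @param intercept Absorbance at zero concentration.
#' @param r2 Calibration coefficient of determination (informational).
#' @return A \code{standard_curve} object.
#' @export
standard_curve <- function(slope = 0.0721, intercept = 0.069, r2 = 0.9987) {
  if (!is.finite(slope) || slope == 0) stop("slope must be finite and non-zero")
  structure(list(slope = slope, intercept = intercept, r2 = r2),
            class = "standard_curve")
}

#' Peptide content from an absorbance reading
#'
#' Inverts the linear standard curve, \code{x = (y - intercept) / slope},
#' and applies the dilution factor. A result below zero (reading under the
#' blank) is returned with a warning.
#'
#' @param absorbance Measured absorbance.
#' @param curve A [standard_curve()].
#' @param dilution Dilution factor (> 0, default 1).
#' @return Concentration in mg/mL.
#' @examples
#' peptide_content(0.790)  # 10 mg/mL on the default curve
#' @export
peptide_content <- function(absorbance, curve = standard_curve(), dilution = 1) {
  stopifnot(inherits(curve, "standard_curve"), is.finite(absorbance))
  if (!is.finite(dilution) || dilution <= 0) stop("dilution must be positive")
  x <- (absorbance - curve$intercept) / curve$slope * dilution
  if (x < 0) warning("absorbance below blank: negative concentration ",
                     format(x, digits = 4))
  x
}

#' ANS surface hydrophobicity (H0) from a dilution series
#'
#' H0 is the initial slope of fluorescence intensity against protein
#' concentration, fitted by ordinary least squares. By default the whole
#' series is used; \code{k_lowest} restricts the fit to the k lowest
#' concentrations for a stricter reading of "initial".
#'
#' @param concentration Protein concentrations (mg/mL), at least two distinct.
#' @param intensity Fluorescence intensities, same length.
#' @param k_lowest Optional number of lowest-concentration points to fit.
#' @return List with \code{h0} (slope), \code{intercept}, \code{r2}.
#' @examples
#' surface_hydrophobicity(c(0, 1, 2), c(0, 10, 20))$h0  # 10
#' @export
surface_hydrophobicity <- function(concentration, intensity, k_lowest = NULL) {
  stopifnot(length(concentration) == length(intensity),
            all(is.finite(concentration)), all(is.finite(intensity)))
  if (!is.null(k_lowest)) {
    ord <- order(concentration)
    keep <- ord[seq_len(min(k_lowest, length(ord)))]
    concentration <- concentration[keep]
    intensity <- intensity[keep]
  }
  if (length(unique(concentration)) < 2L)
    stop("degenerate fit: at least two distinct concentrations are required")
  fit <- stats::lm(intensity ~ concentration)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((intensity - mean(intensity))^2)
  list(h0 = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Prolamin extraction rate
#'
#' \code{100 * extract_protein / seed_prolamin}: protein recovered in the
#' extract as a percentage of the prolamin content of the seed, in any
#' consistent mass units.
#'
#' @param extract_protein Protein mass (or content) in the extract.
#' @param seed_prolamin Prolamin mass (or content) in the seed; must be > 0.
#' @return Percent.
#' @examples
#' extraction_rate(0.42, 0.60)  # 70
#' @export
extraction_rate <- function(extract_protein, seed_prolamin) {
  stopifnot(is.finite(extract_protein), is.finite(seed_prolamin))
  if (seed_prolamin <= 0) stop("seed prolamin content must be positive")
  if (extract_protein < 0) stop("extract protein content must be non-negative")
  100 * extract_protein / seed_prolamin
}
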