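# Seeded generators for every input class the pipeline consumes, each
# returning ground truth computed by an independent straight-line code path
# so the generators can serve as oracles for the analysis modules.

# One named RNG stream per generator: the stream seed depends only on the
# user seed and the generator name, so adding a generator never shifts the
# draws of another. Result stays below 2^31 - 1.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (abs(as.integer(seed)) %% 1048576L) * 2011L + (h %% 2011L)
}

with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(derive_seed(seed, name))
  force(code)
}

#' Default prolamin-like residue sampling weights
#'
#' Elevated Gln, Pro, Leu, Ala and Phe, mimicking the composition bias of
#' cereal prolamin storage proteins; remaining mass spread over the other
#' residues.
#'
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
prolamin_composition <- function() {
  w <- stats::setNames(rep(0.45 / 15, 20), residue_table()$one_letter)
  w[c("Q", "P", "L", "A", "F")] <- c(0.18, 0.09, 0.13, 0.10, 0.05)
  w / sum(w)
}

# Naive, digestion-module-independent site scan used for generator truth.
naive_sites <- function(sequence, p1, blockers) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- integer(0)
  if (length(chars) < 2L) return(out)
  for (i in seq_len(length(chars) - 1L)) {
    if (chars[i] %in% p1 && !(chars[i + 1L] %in% blockers))
      out <- c(out, i)
  }
  out
}

#' Generate synthetic protein sequences with cleavage-site ground truth
#'
#' Residues are sampled i.i.d. from \code{composition}. For each protein the
#' true cleavage-site lists under the default pepsin (pH > 2) and trypsin
#' tables are computed by an independent naive scan (not by the digestion
#' module), making them valid oracles.
#'
#' @param seed Integer seed.
#' @param n_proteins Number of sequences.
#' @param length_range \code{c(min, max)} residues, min >= 2.
#' @param composition Named sampling weights over the 20 residues
#'   (default [prolamin_composition()]).
#' @return List with \code{proteins} (list of [protein_record()]) and
#'   \code{true_sites} (per protein, list with \code{pepsin} and
#'   \code{trypsin} bond-index vectors).
#' @export
gen_proteins <- function(seed, n_proteins = 10L, length_range = c(50L, 300L),
                         composition = prolamin_composition()) {
  stopifnot(n_proteins >= 1L, length_range[1] >= 2L,
            length_range[1] <= length_range[2])
  if (is.null(names(composition)) || any(composition < 0) ||
      sum(composition) <= 0)
    stop("composition must be named, non-negative, and not all zero")
  alphabet <- names(composition)
  if (!all(alphabet %in% residue_table()$one_letter))
    stop("composition names must be canonical one-letter codes")
  with_stream(seed, "proteins", {
    proteins <- vector("list", n_proteins)
    truths <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      len <- sample(length_range[1]:length_range[2], 1L)
      seqc <- paste(sample(alphabet, len, replace = TRUE,
                           prob = composition / sum(composition)),
                    collapse = "")
      proteins[[i]] <- protein_record(sprintf("synthetic_%03d", i), seqc)
      truths[[i]] <- list(
        pepsin = naive_sites(seqc, c("F", "L", "W", "Y"), "P"),
        trypsin = naive_sites(seqc, c("K", "R"), "P")
      )
    }
    list(proteins = proteins, true_sites = truths)
  })
}

#' Generate a random amino-acid profile with known index truths
#'
#' Contents are drawn uniformly per residue; the returned truths (TAA, EAA,
#' PER regressions, TAV class totals) are computed by straight-line
#' arithmetic inside the generator, independently of the nutrition module.
#'
#' @param seed Integer seed.
#' @param content_max Upper bound of the uniform content draw (g/100 g).
#' @return List with \code{profile} (an [amino_acid_profile()]) and
#'   \code{truth} (list: \code{taa}, \code{eaa}, \code{per1}, \code{per2},
#'   \code{per3}, \code{tft}, \code{tbt}, \code{tst}).
#' @export
gen_profile <- function(seed, content_max = 20) {
  stopifnot(content_max > 0)
  with_stream(seed, "profile", {
    rt <- residue_table()
    content <- stats::setNames(stats::runif(20, 0, content_max),
                               rt$three_letter)
    x <- content
    truth <- list(
      taa = sum(x),
      eaa = x[["Thr"]] + x[["Val"]] + x[["Met"]] + x[["Ile"]] + x[["Leu"]] +
        x[["Phe"]] + x[["Lys"]] + x[["Trp"]],
      per1 = -0.684 + 0.456 * x[["Leu"]] - 0.047 * x[["Pro"]],
      per2 = -0.468 + 0.454 * x[["Leu"]] - 0.105 * x[["Tyr"]],
      per3 = -1.816 + 0.435 * x[["Met"]] + 0.78 * x[["Leu"]] +
        0.211 * x[["His"]] - 0.944 * x[["Tyr"]],
      tft = 1000 * (x[["Glu"]] / 30 + x[["Asp"]] / 100),
      tbt = 1000 * (x[["Val"]] / 150 + x[["Met"]] / 30 + x[["Ile"]] / 90 +
                      x[["Leu"]] / 380 + x[["Phe"]] / 150 + x[["His"]] / 20 +
                      x[["Arg"]] / 10),
      tst = 1000 * (x[["Thr"]] / 260 + x[["Ser"]] / 150 + x[["Gly"]] / 110)
    )
    list(profile = amino_acid_profile(content, sprintf("synthetic_%d", seed)),
         truth = truth)
  })
}

# Independent window lookup for generator truth (duplicates, on purpose, the
# amide I assignment logic in naive form).
naive_structure_of <- function(center) {
  if (center >= 1615 && center <= 1637) return("beta_sheet")
  if (center > 1637 && center <= 1645) return("random_coil")
  if (center >= 1646 && center <= 1664) return("alpha_helix")
  if (center > 1664 && center <= 1681) return("beta_turn")
  if (center >= 1682 && center <= 1700) return("beta_sheet")
  "unassigned"
}

#' Generate a synthetic amide I spectrum with known structure fractions
#'
#' A sum of Gaussian bands on a 0.5 cm^-1 grid plus seeded Gaussian noise and
#' an optional linear baseline. When \code{bands} is \code{NULL}, one band per
#' secondary structure is drawn: centers uniform within the amide I
#' assignment windows (beta-sheet from its low-wavenumber window) with a
#' 3 cm^-1 margin, widths (Gaussian sigma) uniform in 3-5.5 cm^-1 (FWHM
#' 7-13 cm^-1, the derivative-resolved sub-band regime, so that the four
#' components are spectroscopically resolvable and the truth identifiable),
#' and areas uniform in 10-50 then kept as drawn. True fractions are the normalised
#' areas grouped by the window containing each center, computed by an
#' independent naive lookup.
#'
#' @param seed Integer seed.
#' @param bands Optional data.frame/matrix-like with columns \code{center},
#'   \code{sigma}, \code{area}; \code{NULL} draws a random 4-band set.
#' @param grid Wavenumber range, default \code{c(1580, 1720)}.
#' @param snr_db Signal-to-noise ratio in dB (peak signal vs noise sigma);
#'   \code{Inf} for noiseless. Default 40.
#' @param baseline \code{c(intercept, slope)} of an added linear baseline
#'   (default none).
#' @param kind Spectrum kind label.
#' @return List with \code{spectrum} (a [spectrum()]), \code{bands} (the
#'   generating parameters) and \code{true_fractions} (named percentages
#'   summing to 100).
#' @export
gen_spectrum <- function(seed, bands = NULL, grid = c(1580, 1720),
                         snr_db = 40, baseline = c(0, 0),
                         kind = c("ftir", "raman")) {
  kind <- match.arg(kind)
  with_stream(seed, "spectrum", {
    if (is.null(bands)) {
      windows <- list(beta_sheet = c(1615, 1637), random_coil = c(1637, 1645),
                      alpha_helix = c(1646, 1664), beta_turn = c(1664, 1681))
      margin <- 3
      bands <- data.frame(
        center = vapply(windows, function(w)
          stats::runif(1, w[1] + margin, w[2] - margin), 0),
        sigma = stats::runif(4, 3, 5.5),
        area = stats::runif(4, 10, 50)
      )
    }
    bands <- as.data.frame(bands)
    stopifnot(all(c("center", "sigma", "area") %in% names(bands)))
    x <- seq(grid[1], grid[2], by = 0.5)
    if (any(bands$center < grid[1] | bands$center > grid[2]))
      stop("band center outside the wavenumber grid")
    signal <- rowSums(vapply(seq_len(nrow(bands)), function(i) {
      amp <- bands$area[i] / (bands$sigma[i] * sqrt(2 * pi))
      amp * exp(-0.5 * ((x - bands$center[i]) / bands$sigma[i])^2)
    }, numeric(length(x))))
    noise_sd <- if (is.finite(snr_db)) max(signal) / 10^(snr_db / 20) else 0
    y <- signal + stats::rnorm(length(x), 0, noise_sd) +
      baseline[1] + baseline[2] * x
    struct <- vapply(bands$center, naive_structure_of, "")
    if (any(struct == "unassigned"))
      stop("generated band center outside all assignment windows")
    tot <- sum(bands$area)
    truth <- vapply(c("beta_sheet", "random_coil", "alpha_helix", "beta_turn"),
                    function(s) 100 * sum(bands$area[struct == s]) / tot, 0)
    list(spectrum = spectrum(x, y, kind), bands = bands,
         true_fractions = truth)
  })
}

#' Generate plate readings consistent with a chosen true inhibition
#'
#' Builds the four absorbances so that the noiseless inhibition equals
#' \code{truth_percent}, then adds independent Gaussian reading noise.
#'
#' @param seed Integer seed.
#' @param truth_percent True inhibition (default 50).
#' @param noise_sd Absorbance noise sigma (default 0, noiseless).
#' @param control_window Control absorbance window \code{a_c - a_cb}
#'   (default 0.8).
#' @param blank Blank absorbance level (default 0.1).
#' @return List with \code{a_s}, \code{a_sb}, \code{a_c}, \code{a_cb} and
#'   \code{truth_percent}.
#' @export
gen_plate <- function(seed, truth_percent = 50, noise_sd = 0,
                      control_window = 0.8, blank = 0.1) {
  stopifnot(noise_sd >= 0, control_window > 0)
  with_stream(seed, "plate", {
    eps <- stats::rnorm(4, 0, noise_sd)
    list(a_s = blank + (1 - truth_percent / 100) * control_window + eps[1],
         a_sb = blank + eps[2],
         a_c = blank + control_window + eps[3],
         a_cb = blank + eps[4],
         truth_percent = truth_percent)
  })
}
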