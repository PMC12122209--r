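# Synthetic two-view data with class imbalance and complementary per-view
# separability, for testing the full pipeline without any image download.

#' Configuration for the synthetic two-view generator
#'
#' The generator draws class-conditional spherical Gaussians per view.
#' `delta1`/`delta2` are the total standardized mean shifts (Euclidean norm
#' of the between-class mean difference, in units of `noise_sd`) of view 1
#' and view 2; the shift is spread evenly over the signal axes (a fraction
#' `overlap_axis_fraction` of each view's dimensions), so the overall class
#' separation is `delta` regardless of dimension.
#'
#' A view "favors" a class through `favored_sd_scale`: the favored class
#' (P in view 1, A in view 2) is drawn with standard deviation
#' `favored_sd_scale * noise_sd`. Linear separation alone cannot produce a
#' sensitivity/specificity asymmetry at a symmetric threshold; a tighter
#' favored class spills across the decision boundary less often than the
#' diffuse class, which is what makes view 1 presence-sensitive and view 2
#' absence-sensitive. At the default `favored_sd_scale = 1` both classes
#' share the same spherical covariance and no asymmetry is induced.
#'
#' Defaults mirror the imbalanced histopathology setting the package
#' targets: 180 presence vs 57 absence samples (an approximately 3:1
#' imbalance, 76% vs 24%).
#'
#' @param n_P,n_A Number of presence / absence samples.
#' @param d1,d2 Feature dimensions of the two views. The defaults (64, 48)
#'   are large enough to exercise high-dimensional behavior while keeping
#'   tests at seconds scale.
#' @param delta1,delta2 Total standardized class separation per view.
#' @param overlap_axis_fraction Fraction of dimensions carrying signal.
#' @param noise_sd Within-class standard deviation of the unfavored class.
#' @param favored_sd_scale Standard-deviation multiplier for the favored
#'   class (P in view 1, A in view 2); values below 1 induce the
#'   sensitivity/specificity asymmetry.
#' @param seed Integer seed; a fixed seed reproduces output bit-exactly.
#' @return An object of class `synth_config` (a list of the above).
#' @export
synth_config <- function(n_P = 180, n_A = 57, d1 = 64, d2 = 48,
                         delta1 = 2, delta2 = 2,
                         overlap_axis_fraction = 0.25,
                         noise_sd = 1, favored_sd_scale = 1, seed = 1) {
  cfg <- list(n_P = as.integer(n_P), n_A = as.integer(n_A),
              d1 = as.integer(d1), d2 = as.integer(d2),
              delta1 = delta1, delta2 = delta2,
              overlap_axis_fraction = overlap_axis_fraction,
              noise_sd = noise_sd, favored_sd_scale = favored_sd_scale,
              seed = as.integer(seed))
  if (cfg$n_P < 1 || cfg$n_A < 1) stop_input("n_P and n_A must be positive")
  if (cfg$d1 < 1 || cfg$d2 < 1) stop_input("feature dimensions must be positive")
  if (cfg$noise_sd <= 0) stop_input("noise_sd must be > 0")
  if (cfg$favored_sd_scale <= 0) stop_input("favored_sd_scale must be > 0")
  if (cfg$overlap_axis_fraction <= 0 || cfg$overlap_axis_fraction > 1) {
    stop_input("overlap_axis_fraction must be in (0, 1]")
  }
  if (cfg$delta1 < 0 || cfg$delta2 < 0) stop_input("separations must be >= 0")
  class(cfg) <- "synth_config"
  cfg
}

#' Preset emulating complementary view asymmetry under class imbalance
#'
#' Returns a [synth_config()] whose view 1 yields a classifier with higher
#' sensitivity than specificity and view 2 the reverse, when trained with
#' [train_view_classifier()] at defaults. Both views get total separation
#' `strength`; the favored class of each view (P in view 1, A in view 2) is
#' tightened exponentially, `favored_sd_scale = exp(-strength)`, so the
#' asymmetry vanishes continuously as `strength` approaches 0. The
#' tightening must be strong because an unweighted soft-margin SVM under
#' 3:1 imbalance shifts its boundary toward the minority class; only a
#' sharply concentrated favored class keeps the per-view specialization
#' visible in held-out sensitivity/specificity.
#'
#' @param imbalance_ratio Ratio `n_P / n_A`, at least 1.
#' @param strength Separation strength in (0, 5].
#' @param n_A Number of absence (minority) samples; default 57.
#' @param n_P Number of presence samples; defaults to
#'   `round(imbalance_ratio * n_A)` but can be set directly.
#' @param seed Integer seed.
#' @return A [synth_config()].
#' @export
asymmetry_preset <- function(imbalance_ratio, strength,
                             n_A = 57, n_P = NULL, seed = 1) {
  if (imbalance_ratio < 1) stop_input("imbalance_ratio must be >= 1")
  if (strength <= 0 || strength > 5) stop_input("strength must be in (0, 5]")
  if (is.null(n_P)) n_P <- round(imbalance_ratio * n_A)
  synth_config(n_P = n_P, n_A = n_A,
               delta1 = strength, delta2 = strength,
               favored_sd_scale = exp(-strength),
               seed = seed)
}

# One class-conditional Gaussian view. The class mean of A sits at the
# origin; P is shifted by delta/sqrt(m) * noise_sd on each of the m signal
# axes (the first m columns), giving total standardized separation delta.
make_view_matrix <- function(labels, d, delta, overlap_axis_fraction,
                             noise_sd, favored, favored_sd_scale) {
  n <- length(labels)
  m <- max(1L, round(overlap_axis_fraction * d))
  shift <- delta / sqrt(m) * noise_sd
  sds <- ifelse(labels == favored, favored_sd_scale * noise_sd, noise_sd)
  mat <- matrix(stats::rnorm(n * d), nrow = n, ncol = d) * sds
  mat[labels == "P", seq_len(m)] <- mat[labels == "P", seq_len(m), drop = FALSE] + shift
  mat
}

#' Generate a synthetic two-view dataset
#'
#' Draws both feature views from class-conditional spherical Gaussians per
#' the configuration (see [synth_config()]): view 1 is oriented to favor the
#' presence class, view 2 the absence class. The manifest synthesizes
#' categories consistently with the binary labels (absence samples become
#' leukoplakia without dysplasia; presence samples alternate between
#' leukoplakia with dysplasia and OSCC). Output is bit-exactly reproducible
#' for a fixed config.
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_dataset`: list with `manifest` (labels
#'   merged), `view1`, `view2` ([feature_view()]s sharing sample order),
#'   `truth` (named label vector), and `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_P + config$n_A
  ids <- sprintf("s%04d", seq_len(n))
  labels <- c(rep("P", config$n_P), rep("A", config$n_A))

  # presence categories alternate between dysplastic leukoplakia and OSCC
  p_cat <- rep(c("leukoplakia_with_dysplasia", "oscc"), length.out = config$n_P)
  category <- c(p_cat, rep("leukoplakia_without_dysplasia", config$n_A))
  manifest <- merge_labels(as_manifest(ids, category))

  set.seed(config$seed)
  m1 <- make_view_matrix(labels, config$d1, config$delta1,
                         config$overlap_axis_fraction, config$noise_sd,
                         favored = "P", config$favored_sd_scale)
  m2 <- make_view_matrix(labels, config$d2, config$delta2,
                         config$overlap_axis_fraction, config$noise_sd,
                         favored = "A", config$favored_sd_scale)

  structure(list(
    manifest = manifest,
    view1 = feature_view("view1", ids, m1),
    view2 = feature_view("view2", ids, m2),
    truth = stats::setNames(labels, ids),
    config = config
  ), class = "synth_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes the manifest CSV (with a `label` truth column appended), and one
#' delimited text file per view.
#'
#' @param dataset A `synth_dataset` from [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(dir, "manifest.csv")
  man <- dataset$manifest[, c("sample_id", "image_path", "category", "label")]
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE, na = "")
  v1 <- file.path(dir, "view1.csv")
  v2 <- file.path(dir, "view2.csv")
  write_feature_view(dataset$view1, v1)
  write_feature_view(dataset$view2, v2)
  invisible(c(manifest = man_path, view1 = v1, view2 = v2))
}
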