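## Per-family classification of active-site conformational behaviour from
## the distribution of all-vs-all functional-atom RMSD values. The four
## paradigms: inherently rigid (tight distribution, mean below ~1 Angstrom),
## inherently flexible (unimodal, centred above ~1 Angstrom), open/closed
## (bimodal: two distinct conformations without intermediates), and
## extensively variable (irregular, overdispersed shape). Families with too
## few conserved sites are left unclassified.

## population skewness
skewness_g1 <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

## 1- vs 2-component Gaussian mixture comparison (BIC maximised, mclust
## convention); returns the BIC difference and the component separation in
## units of the pooled within-component standard deviation.
## mclustBIC must be imported: Mclust() resolves it in the caller's frame.
#' @importFrom mclust Mclust mclustBIC
mixture_evidence <- function(x) {
  fit1 <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = 1, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  fit2 <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit2) || is.null(fit1)) {
    return(list(delta_bic = NA_real_, separation = NA_real_))
  }
  mu <- fit2$parameters$mean
  var_ <- fit2$parameters$variance$sigmasq
  if (length(var_) == 1) var_ <- rep(var_, 2)
  pro <- fit2$parameters$pro
  pooled_sd <- sqrt(sum(pro * var_))
  list(delta_bic = as.numeric(fit2$bic - fit1$bic),
       separation = abs(diff(mu)) / pooled_sd)
}

#' Paradigm classification thresholds
#'
#' Defaults were calibrated once on the synthetic ensemble presets (see the
#' methods vignette): a clean two-state family separates its mixture
#' components by well over 5 pooled sigmas, a drifting (extensively
#' variable) family by 2-4, and unimodal families stay under 2; the
#' rigid/flexible boundary on the mean weighted RMSD reuses the 0.5 Angstrom
#' experimental-error limit used throughout the package.
#'
#' @param min_sites minimum number of homologous sites for a call.
#' @param rigid_mean mean RMSD boundary between rigid and flexible
#'   behaviour (Angstrom).
#' @param bic_margin BIC advantage the 2-component mixture must reach for
#'   multimodality evidence.
#' @param separation_factor minimum component separation, in pooled-sigma
#'   units, for a clean two-state (bimodal) call.
#' @param overlap_separation component separation above which overlapping
#'   multimodality counts as extensive variability.
#' @param dispersion_factor sd/mean ratio above which an overdispersed
#'   distribution is called extensively variable.
#' @return list of thresholds.
#' @export
paradigm_thresholds <- function(min_sites = 50, rigid_mean = 0.5,
                                bic_margin = 10, separation_factor = 5,
                                overlap_separation = 2,
                                dispersion_factor = 0.5) {
  list(min_sites = min_sites, rigid_mean = rigid_mean,
       bic_margin = bic_margin, separation_factor = separation_factor,
       overlap_separation = overlap_separation,
       dispersion_factor = dispersion_factor)
}

#' Classify the conformational paradigm of an enzyme family
#'
#' Decision rule over the all-vs-all functional-atom RMSD values of the
#' family's conserved sites: (1) clean bimodality (2-component Gaussian
#' mixture beats 1 component by more than `bic_margin` BIC with component
#' separation above `separation_factor` pooled sigmas) -> open/closed;
#' (2) otherwise moderate multimodality (separation above
#' `overlap_separation`) or sd > `dispersion_factor` * mean -> extensively
#' variable; (3) otherwise mean below `rigid_mean` -> inherently rigid, else
#' inherently flexible. Families with fewer than `min_sites` sites (or fewer
#' than 2 RMSD values) are unclassified.
#'
#' @param rmsd_values numeric vector of all-vs-all functional RMSDs
#'   (Angstrom), conserved sites only.
#' @param n_sites number of homologous site structures behind the values.
#' @param family_id identifier attached to the call.
#' @param thresholds see [paradigm_thresholds()].
#' @return object of class `paradigm_call`: `family_id`, `label` (one of
#'   inherently_rigid, inherently_flexible, open_closed,
#'   extensively_variable, unclassified) and `stats` (mean, sd, skewness,
#'   delta_bic, separation, n_pairs).
#' @export
classify_paradigm <- function(rmsd_values, n_sites,
                              family_id = NA_character_,
                              thresholds = paradigm_thresholds()) {
  rmsd_values <- rmsd_values[is.finite(rmsd_values)]
  stats_ <- list(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
                 delta_bic = NA_real_, separation = NA_real_,
                 n_pairs = length(rmsd_values))
  call_ <- function(label) {
    structure(list(family_id = family_id, label = label, stats = stats_),
              class = "paradigm_call")
  }
  if (n_sites < thresholds$min_sites || length(rmsd_values) < 2) {
    return(call_("unclassified"))
  }
  stats_$mean <- mean(rmsd_values)
  stats_$sd <- stats::sd(rmsd_values)
  stats_$skewness <- skewness_g1(rmsd_values)
  ev <- mixture_evidence(rmsd_values)
  stats_$delta_bic <- ev$delta_bic
  stats_$separation <- ev$separation
  bimodal <- !is.na(ev$delta_bic) && ev$delta_bic > thresholds$bic_margin
  if (bimodal && ev$separation > thresholds$separation_factor) {
    return(call_("open_closed"))
  }
  if ((bimodal && ev$separation > thresholds$overlap_separation) ||
      stats_$sd > thresholds$dispersion_factor * stats_$mean) {
    return(call_("extensively_variable"))
  }
  if (stats_$mean < thresholds$rigid_mean) {
    return(call_("inherently_rigid"))
  }
  call_("inherently_flexible")
}

#' @export
print.paradigm_call <- function(x, ...) {
  cat(sprintf("<paradigm_call%s> %s (mean %.2f A, sd %.2f, skew %.2f, dBIC %.1f, sep %.1f, %d pairs)\n",
              if (!is.na(x$family_id)) paste0(" ", x$family_id) else "",
              x$label, x$stats$mean, x$stats$sd, x$stats$skewness,
              x$stats$delta_bic, x$stats$separation, x$stats$n_pairs))
  invisible(x)
}
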