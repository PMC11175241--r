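#' Default behavioral feature parameters per group
#'
#' Published group means and standard deviations of the six virtual-kiosk
#' behavioral features for healthy controls (`hc`) and aMCI patients
#' (`amci`), with the marginal family used by the generator. Features
#' whose SD is of the order of the mean (scanpath length, hand movement
#' distance, time to completion) are modeled log-normal and the error
#' count negative-binomial, moment-matched to the printed mean/SD;
#' roughly symmetric features (fixation proportion, hand speed) are
#' Gaussian truncated to their physical range.
#'
#' @return Data frame with columns `feature`, `group`, `mean`, `sd`,
#'   `family`, `lower`, `upper`.
#' @export
behavioral_params <- function() {
  f <- BEHAVIORAL_FEATURES
  rbind(
    data.frame(feature = f, group = "hc",
               mean = c(30.59, 56.31, 11.85, 0.23, 50.00, 1.75),
               sd   = c(37.55, 13.98,  6.78, 0.07, 54.94, 1.65)),
    data.frame(feature = f, group = "amci",
               mean = c(52.60, 45.76, 15.95, 0.18, 91.75, 3.50),
               sd   = c(57.42, 16.42, 11.23, 0.06, 84.38, 2.90))
  ) |> transform(
    family = rep(c("lognormal", "truncnorm", "lognormal", "truncnorm",
                   "lognormal", "negbinom"), 2),
    lower = rep(c(0, 0, 0, 0, 0, 0), 2),
    upper = rep(c(Inf, 100, Inf, Inf, Inf, Inf), 2)
  )
}

#' Default neurological feature parameters per group
#'
#' Published group means and standard deviations of the eight selected
#' EEG-SSVEP features (three lobe power ratios, two lobe connectivity
#' ratios, three band connectivity ratios) for healthy controls and aMCI
#' patients. Marginals are Gaussian.
#'
#' @return Data frame with columns `feature`, `group`, `mean`, `sd`,
#'   `family`, `lower`, `upper`.
#' @export
neurological_params <- function() {
  f <- c("5PS-POR-2H", "12PS-POR-1H", "15PS-POR-1H",
         "3PS-POR-α", "5PS-POR-γ",
         "3PS-P-ABR", "10PS-P-ABR", "15PS-P-TBR")
  rbind(
    data.frame(feature = f, group = "hc",
               mean = c(0.74, 0.72, 0.74, 0.95, 0.99, 0.98, 1.04, 0.92),
               sd   = c(0.08, 0.06, 0.07, 0.05, 0.02, 0.08, 0.11, 0.11)),
    data.frame(feature = f, group = "amci",
               mean = c(0.79, 0.82, 0.81, 1.02, 1.01, 1.07, 1.13, 1.04),
               sd   = c(0.05, 0.09, 0.07, 0.05, 0.04, 0.14, 0.17, 0.11))
  ) |> transform(family = "gaussian", lower = -Inf, upper = Inf)
}

#' Default cross-modal correlation targets
#'
#' The significant behavioral-by-neurological Pearson correlations used to
#' couple the two modalities in the synthetic cohort (specified on the
#' latent Gaussian-copula scale).
#'
#' @return Data frame with columns `neurological`, `behavioral`, `r`.
#' @export
cross_modal_targets <- function() {
  data.frame(
    neurological = c("5PS-POR-2H", "5PS-POR-2H", "12PS-POR-1H",
                     "12PS-POR-1H", "12PS-POR-1H", "12PS-POR-1H"),
    behavioral = c("time_to_completion", "n_errors", "fixation_proportion",
                   "hand_speed", "time_to_completion", "n_errors"),
    r = c(0.29, 0.40, -0.35, -0.40, 0.32, 0.35)
  )
}

# inverse-CDF draw for one marginal family from copula uniforms
marginal_quantile <- function(u, family, mean, sd, lower = -Inf,
                              upper = Inf) {
  switch(family,
    gaussian = qnorm(u, mean, sd),
    truncnorm = {
      plo <- pnorm(lower, mean, sd)
      phi <- pnorm(upper, mean, sd)
      qnorm(plo + u * (phi - plo), mean, sd)
    },
    lognormal = {
      s2 <- log(1 + (sd / mean)^2)
      qlnorm(u, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    },
    negbinom = {
      v <- sd^2
      if (v <= mean) stop("negative-binomial needs variance > mean",
                          call. = FALSE)
      qnbinom(u, size = mean^2 / (v - mean), mu = mean)
    },
    stop("unknown marginal family: ", family, call. = FALSE)
  )
}

#' Cohort specification for the joint feature-table generator
#'
#' Collects everything [simulate_cohort()] needs: per-group, per-feature
#' marginal parameters and the cross-modal correlation targets. Defaults
#' are calibrated to the published group statistics of the six behavioral
#' and eight neurological features and the published cross-modal
#' correlations.
#'
#' @param n_per_group Subjects per group.
#' @param behavioral,neurological Parameter tables in the format of
#'   [behavioral_params()] / [neurological_params()]. Either may be `NULL`
#'   to omit the modality.
#' @param cross_modal Correlation targets in the format of
#'   [cross_modal_targets()] (latent-scale; `|r| <= 1`).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 24,
                        behavioral = behavioral_params(),
                        neurological = neurological_params(),
                        cross_modal = cross_modal_targets(),
                        seed = 1L) {
  params <- rbind(behavioral, neurological)
  if (any(params$sd <= 0)) stop("all SDs must be > 0", call. = FALSE)
  if (!is.null(cross_modal) && nrow(cross_modal) > 0 &&
      any(abs(cross_modal$r) > 1)) {
    stop("|correlation| must be <= 1", call. = FALSE)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 behavioral = behavioral, neurological = neurological,
                 cross_modal = cross_modal, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Assemble the latent correlation matrix for one group's feature list and
# verify positive semi-definiteness.
latent_correlation <- function(features, cross_modal) {
  p <- length(features)
  R <- diag(p)
  dimnames(R) <- list(features, features)
  if (!is.null(cross_modal)) {
    for (k in seq_len(nrow(cross_modal))) {
      i <- cross_modal$neurological[k]
      j <- cross_modal$behavioral[k]
      if (i %in% features && j %in% features) {
        R[i, j] <- R[j, i] <- cross_modal$r[k]
      }
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation specification does not complete to a positive ",
         "semi-definite matrix", call. = FALSE)
  }
  R
}

#' Simulate a joint multimodal feature table
#'
#' Draws `2 * n_per_group` labeled subjects. Within each group, features
#' are sampled through a Gaussian copula: a multivariate normal draw with
#' the requested latent correlation matrix is pushed through each
#' feature's marginal quantile function. Cross-modal correlations are
#' therefore exact on the latent scale and match the Pearson scale for
#' Gaussian marginals (approximately for skewed ones).
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` feature table: `subject_id`, `group`
#'   (factor `hc`/`amci`), then one column per feature.
#' @examples
#' tab <- simulate_cohort(cohort_spec(n_per_group = 10, seed = 3))
#' dim(tab)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  params <- rbind(spec$behavioral, spec$neurological)
  features <- unique(params$feature)
  R <- latent_correlation(features, spec$cross_modal)
  L <- chol_psd(R)
  with_seed(spec$seed, {
    out <- lapply(c("hc", "amci"), function(g) {
      pg <- params[params$group == g, ]
      pg <- pg[match(features, pg$feature), ]
      Z <- matrix(rnorm(spec$n_per_group * length(features)),
                  spec$n_per_group) %*% L
      U <- pnorm(Z)
      X <- vapply(seq_along(features), function(j) {
        marginal_quantile(U[, j], pg$family[j], pg$mean[j], pg$sd[j],
                          pg$lower[j], pg$upper[j])
      }, numeric(spec$n_per_group))
      colnames(X) <- features
      data.frame(group = g, X, check.names = FALSE)
    })
    tab <- do.call(rbind, out)
    tab <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(tab))), tab)
    tab$group <- factor(tab$group, levels = c("hc", "amci"))
    rownames(tab) <- NULL
    tab
  })
}

# Cholesky-like factor tolerating a PSD (not strictly PD) matrix.
chol_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

#' Simulate a cohort of virtual-kiosk sessions and extract their features
#'
#' Draws per-subject behavioral targets from the group's marginal
#' distributions (see [behavioral_params()]), synthesizes one session log
#' per subject with [simulate_vr_session()], and runs
#' [extract_behavioral_features()] on each emitted log, so the returned
#' table reflects the full generator-to-extractor round trip.
#'
#' @param n Number of subjects.
#' @param group `"hc"` or `"amci"`.
#' @param seed Integer seed.
#' @param params Behavioral parameter table (default [behavioral_params()]).
#' @param gaze_rate Gaze/hand stream rate passed to the session generator.
#' @return Data frame of extracted features, one row per subject.
#' @export
simulate_vr_cohort <- function(n, group = c("hc", "amci"), seed,
                               params = behavioral_params(),
                               gaze_rate = 50) {
  group <- match.arg(group)
  pg <- params[params$group == group, ]
  rownames(pg) <- pg$feature
  with_seed(seed, {
    draw <- function(feat) {
      r <- pg[feat, ]
      marginal_quantile(runif(n), r$family, r$mean, r$sd, r$lower, r$upper)
    }
    # hand speed is drawn from its own marginal and the session's hand
    # distance derived (speed x duration): drawing distance instead would
    # distort the emergent speed badly under the heavy-tailed durations
    targets <- data.frame(
      time_to_completion = pmax(draw("time_to_completion"), 1),
      n_errors = draw("n_errors"),
      scanpath_length = draw("scanpath_length"),
      fixation_proportion = draw("fixation_proportion"),
      hand_speed = draw("hand_speed")
    )
    seeds <- sample.int(.Machine$integer.max, n)
    rows <- lapply(seq_len(n), function(i) {
      log <- simulate_vr_session(as.list(targets[i, ]), seed = seeds[i],
                                 gaze_rate = gaze_rate,
                                 hand_rate = gaze_rate)
      extract_behavioral_features(log)
    })
    do.call(rbind, rows)
  })
}
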