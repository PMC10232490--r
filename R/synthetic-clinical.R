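#' Simulate clinical records with cluster-dependent hazards
#'
#' Overall-survival event times are exponential with the hazard of the
#' sample's immune cluster; censoring is an independent exponential
#' truncated at `max_follow_up` months. Progression-free survival is
#' generated as a uniform fraction of the OS time with the same event
#' indicator. Stage, treatment arm and PET response are drawn from
#' configurable categorical distributions.
#'
#' @param labels integer cluster label (1..4) per sample.
#' @param hazard_by_cluster four positive event rates (per month).
#' @param censor_rate exponential censoring rate (0 = no random
#'   censoring).
#' @param max_follow_up administrative censoring time in months (may be
#'   `Inf`).
#' @param seed integer seed.
#' @param sample_ids sample identifiers (default Sample_001..).
#' @param stage_probs probabilities for stages I..IV.
#' @param treatment_probs named probabilities for treatment arms.
#' @param pet_probs probabilities for (responder, non-responder).
#' @return data.frame: sample_id, os_months, os_event, pfs_months,
#'   pfs_event, stage, treatment, pet_response, cluster.
#' @export
simulate_clinical <- function(labels,
                              hazard_by_cluster = c(0.02, 0.08, 0.04, 0.05),
                              censor_rate = 0.01,
                              max_follow_up = 120,
                              seed = 1,
                              sample_ids = sprintf("Sample_%03d",
                                                   seq_along(labels)),
                              stage_probs = c(0.1, 0.35, 0.4, 0.15),
                              treatment_probs = c(CF = 0.5, DCF = 0.5),
                              pet_probs = c(0.55, 0.45)) {
  if (any(hazard_by_cluster <= 0)) stop("hazards must be positive")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  n <- length(labels)
  stopifnot(all(labels %in% seq_along(hazard_by_cluster)))
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = hazard_by_cluster[labels])
    t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate)
              else rep(Inf, n)
    t_cens <- pmin(t_cens, max_follow_up)
    os <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
    pfs <- os * stats::runif(n, 0.5, 1)
    stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                    prob = stage_probs)
    treatment <- sample(names(treatment_probs), n, replace = TRUE,
                        prob = treatment_probs)
    pet <- sample(c("responder", "non-responder"), n, replace = TRUE,
                  prob = pet_probs)
  })
  data.frame(
    sample_id = sample_ids,
    os_months = os, os_event = os_event,
    pfs_months = pfs, pfs_event = os_event,
    stage = stage, treatment = treatment, pet_response = pet,
    cluster = labels,
    stringsAsFactors = FALSE
  )
}
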