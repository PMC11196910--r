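# Seeded synthetic cohort generator: syndrome-conditional independent
# Bernoulli symptom profiles. Each syndrome has a ranked signature symptom
# set with high presence probabilities, all patients share low-probability
# background findings, and a configurable overlap block makes two syndromes
# partially confusable. Under this model the conditional-probability weight
# w_sd is exactly the generating parameter, which makes parameter-recovery
# tests sharp.

# Signature vocabularies per syndrome, ordered from most to least
# characteristic (pulse/tongue findings, aggravating factors, onset and
# duration attributes typical of each tinnitus pattern).
SIGNATURE_ENTITIES <- list(
  KED = c("Spermatorrhea", "Soreness of loins", "Dreaminess",
          "Wake up early in the morning", "Deficiency and insomnia",
          "Aggravation at night", "Cicadas chirp", "Fine pulse",
          "Scanty fur", "Duration"),
  LFBU = c("Irritable", "Restlessness and insomnia", "Wind sound",
           "String-like pulse", "Tide sound", "Yellow fur",
           "Reddish tongue", "Duration", "Dry mouth",
           "Bitter taste in mouth"),
  PFSI = c("Tastelessness", "Dizziness and heaviness", "Aural fullness",
           "Ear distension", "Slippery pulse", "Slimy fur", "Duration",
           "Yellow fur", "Hearing loss", "Reddish tongue"),
  WFAI = c("Cold or rhinitis", "Tinnitus onset within a month", "Low voice",
           "Thin fur", "Floating pulse", "Duration",
           "Light color of tongue", "Yellow fur", "Hearing loss",
           "Dreaminess"),
  QDSS = c("Feeling emptiness in ear", "Aggravation after work",
           "Aggravation when standing up", "Fine pulse", "Duration",
           "Thin fur", "Light color of tongue", "Anxiety", "Hearing loss",
           "Dreaminess"))

BACKGROUND_ENTITIES <- c(
  "Poor appetite", "Fatigue", "Headache", "Nausea", "Palpitations",
  "Pale complexion", "Night sweats", "Thirst", "Constipation",
  "Loose stools", "Abdominal distension", "Blurred vision",
  "Chest tightness", "Cold limbs", "Dizziness")

#' Default synthetic cohort configuration
#'
#' Five syndromes with class sizes 339 (KED), 307 (LFBU), 194 (PFSI),
#' 270 (QDSS), 155 (WFAI) — 1265 patients in total. Each syndrome has 10
#' signature entities with presence probabilities spread from 0.9 down to
#' 0.6 in characteristicness order; 15 background findings are shared by
#' all syndromes at probabilities 0.05-0.2; and the QDSS-specific
#' aggravation/ear-emptiness entities are additionally given a moderate
#' probability (0.3) under KED, so those two patterns are partially
#' confusable, as they are clinically.
#'
#' @param class_sizes Named integer vector, patients per syndrome.
#' @param seed Integer seed driving generation.
#' @param signature_range Probability range spread over each ranked
#'   signature list, high to low.
#' @param background_range Probability range spread over the background
#'   entities.
#' @param overlap_prob Cross-class probability for the QDSS/KED overlap
#'   block (0 disables it).
#' @return A `cohort_config`: list with `class_sizes`, `probs` (full
#'   entity x syndrome Bernoulli matrix), `signature_probs` (the signature
#'   block of `probs`, `NA` elsewhere), `background_entities`,
#'   `overlap_entities` and `seed`.
#' @export
default_config <- function(class_sizes = c(KED = 339, LFBU = 307, PFSI = 194,
                                           QDSS = 270, WFAI = 155),
                           seed = 20260101,
                           signature_range = c(0.9, 0.6),
                           background_range = c(0.05, 0.2),
                           overlap_prob = 0.3) {
  syndromes <- names(class_sizes)
  sigs <- SIGNATURE_ENTITIES[syndromes]
  entities <- sort(unique(c(unlist(sigs), BACKGROUND_ENTITIES)),
                   method = "radix")
  probs <- matrix(0, length(entities), length(syndromes),
                  dimnames = list(entities, syndromes))
  sig_mask <- probs == 1  # all-FALSE logical mask, same shape
  for (s in syndromes) {
    p <- seq(signature_range[1], signature_range[2],
             length.out = length(sigs[[s]]))
    probs[sigs[[s]], s] <- p
    sig_mask[sigs[[s]], s] <- TRUE
  }
  probs[BACKGROUND_ENTITIES, ] <-
    seq(background_range[1], background_range[2],
        length.out = length(BACKGROUND_ENTITIES))
  overlap <- c("Feeling emptiness in ear", "Aggravation after work",
               "Aggravation when standing up")
  if (overlap_prob > 0 && all(c("KED", "QDSS") %in% syndromes))
    probs[overlap, "KED"] <- overlap_prob
  else
    overlap <- character()
  signature_probs <- probs
  signature_probs[!sig_mask] <- NA_real_
  cfg <- structure(list(class_sizes = class_sizes, probs = probs,
                        signature_probs = signature_probs,
                        signature_entities = sigs,
                        background_entities = BACKGROUND_ENTITIES,
                        overlap_entities = union(
                          overlap,
                          entities[rowSums(sig_mask) >= 2]),
                        seed = seed),
                   class = "cohort_config")
  validate_config(cfg)
}

#' Validate a cohort configuration
#'
#' Checks the generator invariants: probabilities in \[0, 1\], class sizes
#' at least 1, and at least one signature entity per syndrome.
#'
#' @param config A `cohort_config`.
#' @return The config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(config$probs < 0) || any(config$probs > 1))
    stop("presence probabilities must lie in [0, 1]", call. = FALSE)
  if (any(config$class_sizes < 1))
    stop("every class size must be at least 1", call. = FALSE)
  none <- names(config$class_sizes)[!vapply(
    config$signature_entities[names(config$class_sizes)],
    function(x) length(x) > 0, logical(1))]
  if (length(none))
    stop(sprintf("syndrome '%s' has no signature entities", none[1]),
         call. = FALSE)
  invisible(config)
}

#' Build a custom cohort configuration
#'
#' Low-level constructor when the defaults are not wanted: supply the full
#' probability matrix directly.
#'
#' @param class_sizes Named integer vector.
#' @param probs Entity x syndrome probability matrix (rownames entities,
#'   colnames covering `names(class_sizes)`).
#' @param seed Integer seed.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(class_sizes, probs, seed = 1) {
  syndromes <- names(class_sizes)
  stopifnot(all(syndromes %in% colnames(probs)))
  sigs <- lapply(syndromes, function(s)
    rownames(probs)[probs[, s] >= 0.5])
  names(sigs) <- syndromes
  cfg <- structure(list(class_sizes = class_sizes,
                        probs = probs[, syndromes, drop = FALSE],
                        signature_probs = probs[, syndromes, drop = FALSE],
                        signature_entities = sigs,
                        background_entities = character(),
                        overlap_entities = character(), seed = seed),
                   class = "cohort_config")
  validate_config(cfg)
}

#' Generate a labeled synthetic cohort
#'
#' For each syndrome `s`, draws `class_sizes[s]` patients; each entity is
#' present independently with its configured probability. A patient drawn
#' with no features at all is redrawn, so every record has at least one
#' feature. Deterministic for a given `config$seed`.
#'
#' @param config A `cohort_config` (see [default_config()]).
#' @return A record tibble (`patient_id`, `features` list-column,
#'   `syndrome`), directly consumable by [build_graph()] and [run_cv()].
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  entities <- rownames(config$probs)
  withr::with_seed(config$seed, {
    recs <- list()
    idx <- 0L
    for (s in names(config$class_sizes)) {
      p <- config$probs[, s]
      for (i in seq_len(config$class_sizes[[s]])) {
        idx <- idx + 1L
        repeat {
          present <- stats::runif(length(entities)) < p
          if (any(present)) break
        }
        recs[[idx]] <- list(patient_id = sprintf("P%04d", idx),
                            features = entities[present], syndrome = s)
      }
    }
    tibble::tibble(
      patient_id = vapply(recs, `[[`, character(1), "patient_id"),
      features = lapply(recs, `[[`, "features"),
      syndrome = vapply(recs, `[[`, character(1), "syndrome"))
  })
}

#' Corrupt a fraction of cohort labels
#'
#' Reassigns exactly `round(rate * n)` labels, chosen at random, each to a
#' different syndrome drawn uniformly from the remaining labels. Used for
#' robustness experiments.
#'
#' @param records Labeled record tibble.
#' @param rate Fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return The records with corrupted labels.
#' @export
corrupt_labels <- function(records, rate, seed = 1) {
  if (rate < 0 || rate > 1)
    stop("corruption rate must lie in [0, 1]", call. = FALSE)
  labs <- unique(records$syndrome)
  if (length(labs) < 2 && rate > 0)
    stop("need at least two classes to corrupt labels", call. = FALSE)
  n_corrupt <- round(rate * nrow(records))
  withr::with_seed(seed, {
    hit <- sample(nrow(records), n_corrupt)
    for (i in hit) {
      records$syndrome[i] <- sample(setdiff(labs, records$syndrome[i]), 1)
    }
  })
  records
}
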