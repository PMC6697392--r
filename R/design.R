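#' Stimulus categories on the humanlikeness continuum
#'
#' Returns the six stimulus categories used throughout the package, ordered
#' along the humanlikeness continuum from mechanoid robots to humans without
#' physical impairments. Exactly the two human categories carry
#' \code{is_human = TRUE}. \code{latent_humanlikeness} is the ground-truth
#' humanlikeness of the category on the 1--5 rating scale; values are placed
#' well inside the scale so that rating noise rarely hits the scale bounds.
#'
#' @return A data frame with columns \code{name}, \code{is_human},
#'   \code{latent_humanlikeness}, one row per category in continuum order.
#' @export
#' @examples
#' uv_categories()
uv_categories <- function() {
  data.frame(
    name = c("mechanoid", "humanoid", "android", "artificial_human",
             "human_phys_impair", "human_no_impair"),
    is_human = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    latent_humanlikeness = c(1.6, 2.2, 3.0, 3.6, 4.05, 4.35),
    stringsAsFactors = FALSE
  )
}

#' Build the stimulus set
#'
#' Creates \code{n_per_category} exemplars for each of the six categories.
#' Exemplars within a category receive small, evenly spaced offsets on the
#' latent humanlikeness value so that per-stimulus regressions have spread
#' within categories (ground truth only; the offsets never reorder
#' categories).
#'
#' @param n_per_category Number of exemplars per category (default 6, as in
#'   the experimental design).
#' @param exemplar_spread Half-range of the within-category latent offsets.
#' @return Data frame with one row per stimulus: \code{id}, \code{category},
#'   \code{exemplar_index}, \code{is_human}, \code{latent_humanlikeness}.
#' @export
#' @examples
#' stim <- build_stimulus_set(6)
#' nrow(stim)  # 36
build_stimulus_set <- function(n_per_category = 6, exemplar_spread = 0.12) {
  if (!is.numeric(n_per_category) || length(n_per_category) != 1 ||
      n_per_category < 1 || n_per_category != round(n_per_category)) {
    stop("`n_per_category` must be a single integer >= 1")
  }
  cats <- uv_categories()
  offs <- if (n_per_category == 1) 0 else
    seq(-exemplar_spread, exemplar_spread, length.out = n_per_category)
  out <- do.call(rbind, lapply(seq_len(nrow(cats)), function(i) {
    data.frame(
      id = sprintf("%s_%02d", cats$name[i], seq_len(n_per_category)),
      category = cats$name[i],
      exemplar_index = seq_len(n_per_category),
      is_human = cats$is_human[i],
      latent_humanlikeness = cats$latent_humanlikeness[i] + offs,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Build rating-task trials
#'
#' Each stimulus is presented \code{repetitions} times; trial order is a
#' seeded random permutation of the full set. Rating columns are created but
#' left \code{NA} (filled by \code{\link{simulate_ratings}} or by observed
#' data).
#'
#' @param stimuli Data frame from \code{\link{build_stimulus_set}}.
#' @param repetitions Presentations per stimulus (default 2: 36 stimuli give
#'   72 rating trials).
#' @param seed Integer seed controlling the presentation order.
#' @return Data frame of trials with columns \code{trial}, \code{stimulus},
#'   \code{category}, \code{is_human}, \code{latent_humanlikeness},
#'   \code{repetition}, and \code{NA} columns \code{likability},
#'   \code{familiarity}, \code{humanlikeness}.
#' @export
build_rating_trials <- function(stimuli, repetitions = 2, seed = 1) {
  if (is.null(stimuli) || nrow(stimuli) == 0)
    stop("`stimuli` must contain at least one stimulus")
  if (!is.numeric(repetitions) || repetitions < 1 ||
      repetitions != round(repetitions))
    stop("`repetitions` must be an integer >= 1")
  idx <- rep(seq_len(nrow(stimuli)), times = repetitions)
  rep_no <- rep(seq_len(repetitions), each = nrow(stimuli))
  ord <- local({
    set.seed(as.integer(seed) %% .Machine$integer.max)
    sample.int(length(idx))
  })
  out <- data.frame(
    trial = seq_along(idx),
    stimulus = stimuli$id[idx][ord],
    category = stimuli$category[idx][ord],
    is_human = stimuli$is_human[idx][ord],
    latent_humanlikeness = stimuli$latent_humanlikeness[idx][ord],
    repetition = rep_no[ord],
    likability = NA_real_,
    familiarity = NA_real_,
    humanlikeness = NA_real_,
    stringsAsFactors = FALSE
  )
  out
}

#' Build the choice-task design
#'
#' Constructs the choice contrasts and trials. Humans without physical
#' impairments serve as the reference compared against every other category;
#' androids serve as the reference against every remaining category except
#' the human reference. With all six categories this yields 5 + 4 = 9
#' contrasts. Each contrast holds \code{trials_per_contrast} trials pairing
#' distinct exemplars, with presentation order balanced: half of the trials
#' start with the reference category, half with the other category.
#'
#' @param stimuli Data frame from \code{\link{build_stimulus_set}} (a subset
#'   of categories is allowed; contrasts are formed among present categories).
#' @param trials_per_contrast Trials per contrast; must be even so order can
#'   be balanced (default 12, giving 108 trials for 9 contrasts).
#' @param seed Integer seed for exemplar pairing and trial order.
#' @return List with elements \code{contrasts} (data frame:
#'   \code{contrast}, \code{reference_category}, \code{other_category}) and
#'   \code{trials} (data frame: \code{trial}, \code{contrast}, \code{first},
#'   \code{second}, \code{first_category}, \code{second_category},
#'   \code{choice}, \code{confidence}; the last two \code{NA} until
#'   simulated or observed).
#' @export
build_choice_design <- function(stimuli, trials_per_contrast = 12, seed = 1) {
  if (trials_per_contrast < 2 || trials_per_contrast %% 2 != 0)
    stop("`trials_per_contrast` must be a positive even integer (order balance)")
  present <- intersect(uv_categories()$name, unique(stimuli$category))
  refs <- intersect(c("human_no_impair", "android"), present)
  if (length(refs) == 0)
    stop("no reference category (human_no_impair or android) among stimuli")
  contrasts <- do.call(rbind, lapply(refs, function(r) {
    others <- setdiff(present, r)
    if (r == "android") others <- setdiff(others, "human_no_impair")
    if (length(others) == 0) return(NULL)
    data.frame(reference_category = r, other_category = others,
               stringsAsFactors = FALSE)
  }))
  contrasts$contrast <- paste(contrasts$reference_category, "vs",
                              contrasts$other_category)
  contrasts <- contrasts[, c("contrast", "reference_category", "other_category")]

  set.seed(as.integer(seed) %% .Machine$integer.max)
  half <- trials_per_contrast / 2
  trials <- do.call(rbind, lapply(seq_len(nrow(contrasts)), function(i) {
    ref_stim <- stimuli$id[stimuli$category == contrasts$reference_category[i]]
    oth_stim <- stimuli$id[stimuli$category == contrasts$other_category[i]]
    pairs <- expand.grid(ref = ref_stim, oth = oth_stim,
                         stringsAsFactors = FALSE)
    if (nrow(pairs) < trials_per_contrast)
      stop("not enough exemplar pairs for `trials_per_contrast`")
    pick <- pairs[sample.int(nrow(pairs), trials_per_contrast), ]
    ref_first <- rep(c(TRUE, FALSE), each = half)
    data.frame(
      contrast = contrasts$contrast[i],
      first = ifelse(ref_first, pick$ref, pick$oth),
      second = ifelse(ref_first, pick$oth, pick$ref),
      first_category = ifelse(ref_first, contrasts$reference_category[i],
                              contrasts$other_category[i]),
      second_category = ifelse(ref_first, contrasts$other_category[i],
                               contrasts$reference_category[i]),
      stringsAsFactors = FALSE
    )
  }))
  trials <- trials[sample.int(nrow(trials)), ]
  trials <- data.frame(trial = seq_len(nrow(trials)), trials,
                       choice = NA_integer_, confidence = NA_real_,
                       stringsAsFactors = FALSE)
  rownames(trials) <- NULL
  list(contrasts = contrasts, trials = trials)
}

#' Event onsets for one scanning session
#'
#' Generates stimulus-onset times for an event-related session: each trial
#' occupies a fixed task period followed by a jittered inter-trial interval
#' drawn uniformly from \code{iti_range} (default 2--6 s).
#'
#' @param n_trials Number of events.
#' @param trial_duration Fixed task time per trial in seconds (stimulus,
#'   blank, and rating screens; default 16 s).
#' @param iti_range Two-element numeric, uniform jitter bounds in seconds.
#' @param lead_in Quiet time before the first onset in seconds (default 10,
#'   so pre-stimulus epoch samples stay inside the session).
#' @param seed Integer seed.
#' @return List with \code{onsets} (seconds, sorted) and \code{duration}
#'   (session length in seconds, padded past the last trial).
#' @export
build_session_onsets <- function(n_trials, trial_duration = 16,
                                 iti_range = c(2, 6), lead_in = 10,
                                 seed = 1) {
  stopifnot(n_trials >= 1, length(iti_range) == 2, iti_range[1] <= iti_range[2])
  set.seed(as.integer(seed) %% .Machine$integer.max)
  itis <- stats::runif(n_trials, iti_range[1], iti_range[2])
  gaps <- trial_duration + itis
  onsets <- lead_in + c(0, cumsum(gaps[-n_trials]))
  list(onsets = onsets, duration = onsets[n_trials] + trial_duration +
         itis[n_trials] + 16)
}
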