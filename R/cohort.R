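#' Psychometric response model for level-based tasks
#'
#' Probability of passing a trial at a given difficulty level for a simulated
#' participant with latent capacity `theta`:
#' `lapse/2 + (1 - lapse) * plogis((theta - level) / slope)`.
#' The lapse rate flattens both asymptotes, bounding the pass probability in
#' `(lapse/2, 1 - lapse/2)`; the function is strictly decreasing in level.
#'
#' @param theta Latent capacity on the level scale.
#' @param slope Psychometric scale parameter, positive; smaller values give a
#'   steeper function.
#' @param lapse Attention-lapse probability in `[0, 0.5)`.
#' @return An object of class `response_model`.
#' @export
response_model <- function(theta, slope = 0.6, lapse = 0.01) {
  if (!is.finite(slope) || slope <= 0) stop("`slope` must be positive")
  if (lapse < 0 || lapse >= 0.5) stop("`lapse` must be in [0, 0.5)")
  structure(list(theta = theta, slope = slope, lapse = lapse),
            class = "response_model")
}

#' Pass probability at a difficulty level
#'
#' @param model A [response_model()].
#' @param level Difficulty level (1--10 in the span game).
#' @return Probability of passing a trial at `level`.
#' @examples
#' pass_probability(response_model(6, slope = 1, lapse = 0), 6)  # 0.5
#' @export
pass_probability <- function(model, level) {
  stopifnot(inherits(model, "response_model"))
  model$lapse / 2 +
    (1 - model$lapse) * stats::plogis((model$theta - level) / model$slope)
}

#' Configuration of the synthetic cohort generator
#'
#' All distributional choices behind the synthetic cohort. Cross-task
#' correlation is induced by a single common factor: each task's latent
#' ability is `loading * F + sqrt(1 - loading^2) * noise`, so two task
#' scores correlate (before measurement attenuation) as the product of their
#' loadings. Defaults are calibration choices targeting the published
#' correlation pattern of the span game with the four reference tasks
#' (0.37 / 0.40 / 0.50 / 0.35), a retest reliability near 0.75, session-1
#' span scores with mean/SD near 4.91/1.42, and transcription-accuracy
#' fixed effects at the published speech-in-noise (0.26, -0.07, 0.01) and
#' accent (0.10, -0.01, 0) estimates.
#'
#' @param n_participants Cohort size (default 250).
#' @param seed Integer seed; all generation is deterministic given it.
#' @param theta_mean,theta_sd Mean and SD of span-game latent capacity on
#'   the ingredient (level) scale.
#' @param slope,lapse Staircase response-model parameters.
#' @param retest_rho Correlation between session-1 and session-2 latent
#'   capacity.
#' @param age_range Age bounds (uniform), in years.
#' @param age_theta_cor Correlation between age and capacity (default 0).
#' @param cross_task_loadings Named common-factor loadings for tasks
#'   `sandwich`, `digit_aud`, `digit_vis`, `free_aud`, `free_vis`.
#' @param digit_mean,digit_sd,digit_slope Digit-span latent capacity mean
#'   (named auditory/visual), SD, and psychometric slope on the list-length
#'   scale.
#' @param recall_p,recall_slope Free-recall mean per-word recall probability
#'   (named auditory/visual) and logit-scale slope on the latent.
#' @param transcription_coefs List with elements `noise` and `accent`, each
#'   `c(intercept, span, age, span_age)` on the logit scale.
#' @param sigma_subject,sigma_item Random-intercept SDs for the transcription
#'   model.
#' @param n_items_noise,n_items_accent Transcription test-trial counts.
#' @param keywords_per_item Keywords per transcription sentence (default 4).
#' @param rating_effects List with elements `affect`, `fatigue`,
#'   `motivation`; each a named vector of task shifts (z-scale) relative to
#'   the span-game reference.
#' @param rating_sigma_participant,rating_sigma_resid Ratings random
#'   intercept and residual SDs.
#' @param ext_loading,ext_resid_sd Extraversion item generation parameters.
#' @param n_digit_trials_per_length,digit_lengths,n_recall_trials,
#'   n_recall_words Design constants of the reference tasks.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_participants = 250L,
    seed = 1L,
    theta_mean = 5.0,
    theta_sd = 1.4,
    slope = 0.6,
    lapse = 0.01,
    retest_rho = 0.84,
    age_range = c(18, 65),
    age_theta_cor = 0,
    cross_task_loadings = c(sandwich = 0.80, digit_aud = 0.54,
                            digit_vis = 0.58, free_aud = 0.72,
                            free_vis = 0.51),
    digit_mean = c(auditory = 6.8, visual = 6.4),
    digit_sd = 1.5,
    digit_slope = 0.7,
    recall_p = c(auditory = 0.43, visual = 0.42),
    recall_slope = 0.55,
    transcription_coefs = list(
      noise = c(intercept = 0, span = 0.26, age = -0.07, span_age = 0.01),
      accent = c(intercept = 0.5, span = 0.10, age = -0.01, span_age = 0)),
    sigma_subject = 0.3,
    sigma_item = 0.3,
    n_items_noise = 16L,
    n_items_accent = 24L,
    keywords_per_item = 4L,
    rating_effects = list(
      affect = c(digit_aud = -0.35, digit_vis = -0.42, free_aud = -0.39,
                 free_vis = -0.45),
      fatigue = c(digit_aud = 0.24, digit_vis = 0.32, free_aud = 0.20,
                  free_vis = 0.20),
      motivation = c(digit_aud = -0.28, digit_vis = -0.23, free_aud = -0.27,
                     free_vis = -0.27)),
    rating_sigma_participant = 0.5,
    rating_sigma_resid = 0.8,
    ext_loading = 0.9,
    ext_resid_sd = 0.8,
    n_digit_trials_per_length = 4L,
    digit_lengths = 2:10,
    n_recall_trials = 6L,
    n_recall_words = 10L) {
  cfg <- as.list(environment())
  if (cfg$n_participants < 0) stop("`n_participants` must be >= 0")
  if (cfg$theta_sd < 0 || cfg$digit_sd < 0 || cfg$sigma_subject < 0 ||
      cfg$sigma_item < 0 || cfg$rating_sigma_participant < 0 ||
      cfg$rating_sigma_resid < 0)
    stop("variance parameters must be >= 0")
  if (abs(cfg$retest_rho) > 1 || abs(cfg$age_theta_cor) > 1)
    stop("correlations must lie in [-1, 1]")
  if (any(abs(cfg$cross_task_loadings) > 1))
    stop("loadings must lie in [-1, 1]")
  needed <- c("sandwich", "digit_aud", "digit_vis", "free_aud", "free_vis")
  if (!all(needed %in% names(cfg$cross_task_loadings)))
    stop("`cross_task_loadings` must name all of: ",
         paste(needed, collapse = ", "))
  class(cfg) <- "generator_config"
  cfg
}

#' Generate participant profiles
#'
#' Draws the latent layer of the cohort: a common cognitive factor, task
#' latents at the configured loadings, session-1 and session-2 span-game
#' capacity correlated at `retest_rho`, uniform ages, balanced
#' counterbalance orders (1--5), and an extraversion latent independent of
#' capacity.
#'
#' @param config A [generator_config()].
#' @return Data.frame of class `participant_profiles`, one row per
#'   participant: `id`, `age`, `counterbalance`, `theta`, `theta_session2`,
#'   latent columns `z_digit_aud`, `z_digit_vis`, `z_free_aud`,
#'   `z_free_vis`, and `extraversion_latent`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(config$n_participants)
  set.seed(as.integer(config$seed))
  lam <- config$cross_task_loadings
  f <- stats::rnorm(n)
  ztask <- function(loading)
    loading * f + sqrt(1 - loading^2) * stats::rnorm(n)
  z_sb <- ztask(lam[["sandwich"]])
  rho <- config$retest_rho
  z_sb2 <- rho * z_sb + sqrt(1 - rho^2) * stats::rnorm(n)
  age_u <- stats::runif(n)
  age <- config$age_range[1] + diff(config$age_range) * age_u
  if (config$age_theta_cor != 0) {
    # reorder a fraction of ages against capacity rank to induce correlation
    r <- config$age_theta_cor
    age <- config$age_range[1] + diff(config$age_range) *
      stats::pnorm(r * z_sb + sqrt(1 - r^2) * stats::qnorm(age_u))
  }
  prof <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    age = round(age, 1),
    counterbalance = if (n) sample(rep(1:5, length.out = n)) else integer(0),
    theta = config$theta_mean + config$theta_sd * z_sb,
    theta_session2 = config$theta_mean + config$theta_sd * z_sb2,
    z_digit_aud = ztask(lam[["digit_aud"]]),
    z_digit_vis = ztask(lam[["digit_vis"]]),
    z_free_aud = ztask(lam[["free_aud"]]),
    z_free_vis = ztask(lam[["free_vis"]]),
    extraversion_latent = stats::rnorm(n),
    stringsAsFactors = FALSE
  )
  class(prof) <- c("participant_profiles", "data.frame")
  prof
}

# built-in pool of simple nouns for free-recall lists, transcription
# keywords and intrusion fillers
word_pool <- function() {
  c("market", "college", "river", "garden", "window", "bottle", "doctor",
    "mountain", "pencil", "bridge", "candle", "forest", "hammer", "island",
    "jacket", "kitchen", "ladder", "mirror", "needle", "orange", "palace",
    "rabbit", "saddle", "table", "umbrella", "valley", "wagon", "yellow",
    "zebra", "anchor", "basket", "camera", "dragon", "engine", "feather",
    "guitar", "helmet", "insect", "jungle", "kettle", "lantern", "magnet",
    "napkin", "ocean", "pillow", "quarter", "ribbon", "shovel", "teacher",
    "unicorn", "village", "walnut", "barrel", "cabin", "desert", "eagle",
    "fabric", "goblet", "harbor", "iron", "jewel", "kite", "lemon",
    "meadow", "nest", "onion", "pear", "quilt", "rose", "stone", "tiger",
    "urn", "vase", "wheel", "yarn", "apron", "bacon", "cactus", "daisy",
    "elbow", "fence", "glove", "hedge", "ivory", "jar", "knee", "leaf",
    "moth", "nut", "oak", "pond", "quill", "rug", "sock", "tent", "vest",
    "wolf", "yacht", "arrow", "bead", "clam", "dome", "ember", "fern",
    "gate", "hill", "ink", "jug", "keel", "loaf", "mane", "note", "owl",
    "peach", "quail", "reef", "sail", "thorn", "vine", "wren", "acorn",
    "bloom", "crate", "drift", "field", "grain", "heron", "inlet", "jetty",
    "knoll", "lodge", "maple", "niche", "otter", "plume", "ridge", "slate",
    "trout", "vault", "wharf", "amber", "birch", "cliff", "dune", "frost",
    "grove", "hawk", "iris", "juniper", "kelp", "lily", "moss", "newt",
    "opal", "pine", "quartz", "raven", "spruce", "tulip", "violet", "willow",
    "badger", "cedar", "dove", "elm", "finch", "gull", "heather", "ibis",
    "jay", "kestrel", "lark", "mink", "nettle", "osprey", "petal", "quince",
    "robin", "sparrow", "teal", "vole", "wasp", "yew", "aspen", "bramble",
    "cobble", "dell", "eddy", "fjord", "glen", "holly", "islet", "jasper",
    "knot", "loch", "mesa", "nook", "orchard", "pebble", "quarry", "rill",
    "summit", "tarn", "upland", "vista", "weir", "zinc", "alder", "brook",
    "copse", "dale", "estuary", "foam", "gorge", "heath", "icicle", "jade",
    "kiln", "lagoon", "marsh", "nectar", "oasis", "prairie", "ravine",
    "shoal", "tundra", "vortex", "willowherb", "zephyr")
}

random_digits <- function(length) sample(1:9, length, replace = TRUE)

corrupt_digits <- function(digits) {
  n <- length(digits)
  if (n >= 2) {
    i <- sample(n - 1, 1)
    if (digits[i] != digits[i + 1]) {
      digits[c(i, i + 1)] <- digits[c(i + 1, i)]
      return(digits)
    }
  }
  # substitute one digit with a different one
  i <- sample(n, 1)
  digits[i] <- sample(setdiff(1:9, digits[i]), 1)
  digits
}

#' Simulate grouped-binomial transcription counts
#'
#' Generates per-sentence keyword counts from the grouped-binomial logistic
#' model with crossed subject and item random intercepts:
#' `logit(p) = b0 + b_span * span + b_age * age + b_int * span * age +
#' u_subject + w_item`, with `n_correct ~ Binomial(k, p)`.
#' Used both inside [generate_dataset()] and directly in parameter-recovery
#' simulations.
#'
#' @param span,age Numeric vectors, one entry per subject.
#' @param n_items Number of sentences.
#' @param coefs `c(intercept, span, age, span_age)` on the logit scale.
#' @param sigma_subject,sigma_item Random-intercept SDs.
#' @param keywords_per_item Keywords per sentence (default 4).
#' @param subject_ids Optional subject labels.
#' @return Data.frame with `subject`, `item`, `n_correct`, `n_missed`,
#'   `span_score`, `age`.
#' @export
simulate_transcription_counts <- function(span, age, n_items, coefs,
                                          sigma_subject = 0.3,
                                          sigma_item = 0.3,
                                          keywords_per_item = 4L,
                                          subject_ids = NULL) {
  stopifnot(length(span) == length(age), length(coefs) == 4)
  n <- length(span)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  u <- stats::rnorm(n, 0, sigma_subject)
  w <- stats::rnorm(n_items, 0, sigma_item)
  grid <- expand.grid(si = seq_len(n), ii = seq_len(n_items))
  eta <- coefs[1] + coefs[2] * span[grid$si] + coefs[3] * age[grid$si] +
    coefs[4] * span[grid$si] * age[grid$si] + u[grid$si] + w[grid$ii]
  p <- stats::plogis(eta)
  n_correct <- stats::rbinom(nrow(grid), keywords_per_item, p)
  data.frame(
    subject = subject_ids[grid$si],
    item = sprintf("I%02d", grid$ii),
    n_correct = n_correct,
    n_missed = keywords_per_item - n_correct,
    span_score = span[grid$si],
    age = age[grid$si],
    stringsAsFactors = FALSE
  )
}

#' Generate the full synthetic trial-level dataset
#'
#' Simulates every task of the validation study for the supplied profiles:
#' span-game staircase sessions 1 and 2 (via [run_session()] with the
#' logistic-with-lapse response model), fixed-ladder digit span (auditory and
#' visual; 4 trials per list length 2--10 with typed digit responses),
#' six-trial 10-word free recall (auditory and visual; typed word
#' responses), speech-in-noise and accent transcription (grouped-binomial
#' keyword counts rendered as typed sentence responses, plus one always-
#' passed catch trial per participant), post-task rating composites for the
#' five session-1 tasks, and the eight-item extraversion questionnaire with
#' an always-passed attention check. All generation is deterministic given
#' the config seed.
#'
#' @param profiles Output of [generate_cohort()].
#' @param config The same [generator_config()].
#' @return A list of class `cohort_dataset` with named trial tables
#'   (`sandwich_s1`, `sandwich_s2`, `digit_span_aud`, `digit_span_vis`,
#'   `free_recall_aud`, `free_recall_vis`, `transcription_noise`,
#'   `transcription_accent`, `ratings`, `extraversion`) and a `manifest`
#'   (seed and config snapshot).
#' @export
generate_dataset <- function(profiles, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(profiles) == 0) stop("`profiles` must be nonempty")
  set.seed(as.integer(config$seed) + 1L)
  n <- nrow(profiles)
  pool <- word_pool()
  rule <- staircase_rule()

  # -- staircase sessions ----------------------------------------------------
  sessions <- function(thetas, session) {
    recs <- lapply(seq_len(n), function(i) {
      m <- response_model(thetas[i], config$slope, config$lapse)
      run_session(function(level) stats::runif(1) < pass_probability(m, level),
                  rule, seed = NULL, participant = profiles$id[i],
                  session = session)
    })
    do.call(rbind, recs)
  }
  sandwich_s1 <- sessions(profiles$theta, 1L)
  sandwich_s2 <- sessions(profiles$theta_session2, 2L)

  # -- fixed-ladder digit span ----------------------------------------------
  digit_table <- function(z, task, ds_mean) {
    theta_ds <- ds_mean + config$digit_sd * z
    lens <- rep(config$digit_lengths, each = config$n_digit_trials_per_length)
    rows <- lapply(seq_len(n), function(i) {
      m <- response_model(theta_ds[i], config$digit_slope, config$lapse)
      p <- pass_probability(m, lens)
      pass <- stats::runif(length(lens)) < p
      targ <- character(length(lens))
      resp <- character(length(lens))
      for (j in seq_along(lens)) {
        d <- random_digits(lens[j])
        targ[j] <- paste(d, collapse = "")
        resp[j] <- if (pass[j]) paste(d, collapse = " ")
          else paste(corrupt_digits(d), collapse = " ")
      }
      data.frame(participant = profiles$id[i], task = task,
                 trial_index = seq_along(lens), list_length = lens,
                 target = targ, response = resp, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  digit_span_aud <- digit_table(profiles$z_digit_aud, "digit_aud",
                                config$digit_mean[["auditory"]])
  digit_span_vis <- digit_table(profiles$z_digit_vis, "digit_vis",
                                config$digit_mean[["visual"]])

  # -- free recall -----------------------------------------------------------
  recall_lists <- lapply(seq_len(config$n_recall_trials), function(t)
    sample(pool, config$n_recall_words))
  intrusions <- setdiff(pool, unlist(recall_lists))
  recall_table <- function(z, task, p_mean) {
    p <- stats::plogis(stats::qlogis(p_mean) + config$recall_slope * z)
    rows <- lapply(seq_len(n), function(i) {
      resp <- character(config$n_recall_trials)
      for (t in seq_len(config$n_recall_trials)) {
        k <- stats::rbinom(1, config$n_recall_words, p[i])
        words <- sample(recall_lists[[t]], k)
        if (stats::runif(1) < 0.3)
          words <- append(words, sample(intrusions, 1),
                          after = sample(0:length(words), 1))
        resp[t] <- paste(words, collapse = " ")
      }
      data.frame(participant = profiles$id[i], task = task,
                 trial_index = seq_len(config$n_recall_trials),
                 targets = vapply(recall_lists, paste, "", collapse = ";"),
                 response = resp, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  free_recall_aud <- recall_table(profiles$z_free_aud, "free_aud",
                                  config$recall_p[["auditory"]])
  free_recall_vis <- recall_table(profiles$z_free_vis, "free_vis",
                                  config$recall_p[["visual"]])

  # -- transcription ---------------------------------------------------------
  # span covariate is the observed session-2 span-game score, as used in the
  # predictive-validity analyses
  s2_scores <- vapply(split(sandwich_s2, sandwich_s2$participant),
                      function(s) score_session(s)$final, numeric(1))
  s2_scores <- s2_scores[profiles$id]
  trans_table <- function(task, n_items, coefs, kw_words) {
    counts <- simulate_transcription_counts(
      span = as.numeric(s2_scores), age = profiles$age, n_items = n_items,
      coefs = coefs, sigma_subject = config$sigma_subject,
      sigma_item = config$sigma_item,
      keywords_per_item = config$keywords_per_item,
      subject_ids = profiles$id)
    kw_by_item <- split(kw_words, rep(seq_len(n_items),
                                      each = config$keywords_per_item))
    resp <- character(nrow(counts))
    item_idx <- as.integer(sub("^I", "", counts$item))
    for (r in seq_len(nrow(counts))) {
      kws <- kw_by_item[[item_idx[r]]]
      got <- if (counts$n_correct[r] > 0)
        sample(kws, counts$n_correct[r]) else character(0)
      resp[r] <- paste(c("the", got), collapse = " ")
    }
    out <- data.frame(participant = counts$subject, task = task,
                      item = counts$item,
                      keywords = vapply(item_idx, function(ii)
                        paste(kw_by_item[[ii]], collapse = ";"), ""),
                      response = resp, age = counts$age,
                      stringsAsFactors = FALSE)
    catch_kw <- c("i", "am", "paying", "attention")
    catch <- data.frame(participant = profiles$id, task = task,
                        item = "catch", keywords = paste(catch_kw,
                                                         collapse = ";"),
                        response = "i am paying attention",
                        age = profiles$age, stringsAsFactors = FALSE)
    rbind(out, catch)
  }
  kw_noise <- sample(pool, config$n_items_noise * config$keywords_per_item)
  kw_accent <- sample(pool, config$n_items_accent * config$keywords_per_item)
  transcription_noise <- trans_table("noise", config$n_items_noise,
                                     config$transcription_coefs$noise,
                                     kw_noise)
  transcription_accent <- trans_table("accent", config$n_items_accent,
                                      config$transcription_coefs$accent,
                                      kw_accent)

  # -- post-task ratings (composites on the z scale) -------------------------
  tasks5 <- c("sandwich", "digit_aud", "digit_vis", "free_aud", "free_vis")
  rating_rows <- lapply(names(config$rating_effects), function(measure) {
    shifts <- c(sandwich = 0, config$rating_effects[[measure]])
    u <- stats::rnorm(n, 0, config$rating_sigma_participant)
    do.call(rbind, lapply(tasks5, function(tk) {
      data.frame(participant = profiles$id, task = tk,
                 counterbalance = profiles$counterbalance,
                 measure = measure,
                 value = shifts[[tk]] + u +
                   stats::rnorm(n, 0, config$rating_sigma_resid),
                 stringsAsFactors = FALSE)
    }))
  })
  ratings <- do.call(rbind, rating_rows)

  # -- extraversion items ----------------------------------------------------
  reverse_items <- c(2L, 5L, 7L)
  ext_rows <- lapply(seq_len(n), function(i) {
    keyed <- round(3 + config$ext_loading * profiles$extraversion_latent[i] +
                     stats::rnorm(8, 0, config$ext_resid_sd))
    keyed <- pmin(pmax(keyed, 1), 5)
    raw <- keyed
    raw[reverse_items] <- 6 - raw[reverse_items]
    data.frame(participant = profiles$id[i],
               item = c(sprintf("ext%02d", 1:8), "attention_check"),
               reverse = c(seq_len(8) %in% reverse_items, FALSE),
               value = c(raw, 5L), stringsAsFactors = FALSE)
  })
  extraversion <- do.call(rbind, ext_rows)

  tables <- list(
    sandwich_s1 = sandwich_s1, sandwich_s2 = sandwich_s2,
    digit_span_aud = digit_span_aud, digit_span_vis = digit_span_vis,
    free_recall_aud = free_recall_aud, free_recall_vis = free_recall_vis,
    transcription_noise = transcription_noise,
    transcription_accent = transcription_accent,
    ratings = ratings, extraversion = extraversion)
  structure(list(tables = tables,
                 manifest = list(seed = config$seed,
                                 config = unclass(config),
                                 n_participants = n)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Synthetic cohort dataset:", x$manifest$n_participants,
      "participants, seed", x$manifest$seed, "\n")
  for (nm in names(x$tables))
    cat(sprintf("  %-22s %6d rows\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}

#' Export a cohort dataset to CSV files
#'
#' Writes one UTF-8 CSV per trial table plus a plain-text `manifest.txt`
#' key-value snapshot of the generating configuration.
#'
#' @param dataset A `cohort_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(dataset$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(dataset$tables[[nm]], p, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  cfg <- dataset$manifest$config
  flat <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.list(v)) v <- unlist(v)
    paste0(k, ": ", paste(if (is.null(names(v))) v else
      paste0(names(v), "=", v), collapse = ", "))
  }, "")
  mp <- file.path(dir, "manifest.txt")
  writeLines(c(paste0("seed: ", dataset$manifest$seed), flat), mp)
  invisible(c(paths, mp))
}
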