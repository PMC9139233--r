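# Synthetic cytometry cohorts: 14 immunophenotypically distinct populations
# on the 13-channel CLL MRD tube, lognormal per-channel intensities,
# uncompensated spectral overlap, doublets/debris, and rare CLL fractions
# down to 0.001% of WBC.

# log10-intensity anchor levels used throughout the profile table
.lv <- c(neg = 1.3, dim = 2.5, pos = 3.3, bright = 4.3)

# Scatter channels are much tighter than fluorescence on a real
# instrument (FSC/SSC CVs of ~10-15%), which is what makes doublet
# discrimination by area/height work.
.profile <- function(fsc_a, fsc_h, ssc, cd5, cd19, cd20, cd22, cd38, cd43,
                     cd45, cd200, kappa, lambda, sd = 0.25,
                     scatter_sd = 0.06, weight = 1) {
  loc <- c(fsc_a, fsc_h, ssc, cd5, cd19, cd20, cd22, cd38, cd43, cd45,
           cd200, kappa, lambda)
  names(loc) <- cll_panel()$name
  sdv <- rep_len(sd, 13L)
  sdv[1:3] <- scatter_sd
  names(sdv) <- names(loc)
  list(weight = weight, loc = loc, sd = sdv)
}

#' Default marker profiles for the 14 event classes
#'
#' Each profile is a list of one or more mixture components, each with a
#' per-channel log10-intensity location and spread. The CLL template is
#' CD5+ CD19+ CD20-dim CD22-dim CD43+ CD200-bright with dim, restricted
#' surface light chain; polytypic B cells are CD5- CD20-bright with a
#' 60:40 kappa:lambda split; hematogones are CD19+ CD38-bright CD45-dim
#' with low surface light chain; aggregates carry the doublet signature
#' (forward-scatter area far above height); debris sits at low scatter.
#'
#' @param atypical_cd20_bright If `TRUE`, the CLL profile carries the
#'   atypical CD20-bright phenotype (CD20 raised to the polytypic-B level)
#'   while keeping the rest of the CLL signature.
#' @param cll_lambda_restricted If `TRUE`, CLL light-chain restriction is
#'   mirrored to lambda instead of kappa.
#' @return Named list of 14 profiles, keyed by [cll_classes()].
#' @export
#' @examples
#' p <- default_profiles()
#' names(p)
default_profiles <- function(atypical_cd20_bright = FALSE,
                             cll_lambda_restricted = FALSE) {
  cll_cd20 <- if (atypical_cd20_bright) 4.6 else 2.5
  cll_k <- if (cll_lambda_restricted) 1.3 else 2.6
  cll_l <- if (cll_lambda_restricted) 2.6 else 1.3
  profiles <- list(
    CLL_cells = list(
      .profile(4.55, 4.50, 3.80, 3.4, 3.2, cll_cd20, 2.3, 2.2, 3.4, 3.7,
               4.3, cll_k, cll_l)
    ),
    aggregates = list(
      .profile(5.00, 4.50, 4.40, 2.8, 2.8, 2.8, 2.8, 2.8, 2.8, 3.5,
               2.8, 2.8, 2.8, sd = 0.45, scatter_sd = 0.15)
    ),
    B_cells = list(
      .profile(4.55, 4.50, 3.80, 1.3, 3.4, 4.3, 3.3, 2.3, 1.4, 4.3,
               2.6, 3.6, 1.3, weight = 0.6),
      .profile(4.55, 4.50, 3.80, 1.3, 3.4, 4.3, 3.3, 2.3, 1.4, 4.3,
               2.6, 1.3, 3.5, weight = 0.4)
    ),
    basophils_dendritic = list(
      .profile(4.60, 4.55, 4.00, 1.5, 1.4, 1.4, 2.5, 3.5, 2.8, 3.7,
               2.8, 1.4, 1.4)
    ),
    blasts = list(
      .profile(4.80, 4.75, 3.90, 1.8, 1.5, 1.4, 2.1, 3.5, 2.5, 3.0,
               2.3, 1.4, 1.4)
    ),
    debris = list(
      .profile(3.40, 3.35, 3.30, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5,
               1.5, 1.5, 1.5, sd = 0.35, scatter_sd = 0.25)
    ),
    erythroblasts = list(
      .profile(4.40, 4.35, 3.40, 1.4, 1.3, 1.3, 1.4, 2.1, 1.6, 1.4,
               1.4, 1.3, 1.3)
    ),
    granulocytes = list(
      .profile(4.75, 4.70, 4.90, 1.4, 1.3, 1.3, 1.6, 2.0, 3.1, 3.3,
               1.4, 1.4, 1.4)
    ),
    hematogones = list(
      .profile(4.50, 4.45, 3.60, 1.4, 3.3, 3.0, 2.9, 4.4, 1.5, 3.1,
               3.0, 1.6, 1.6)
    ),
    monocytes = list(
      .profile(4.80, 4.75, 4.35, 1.6, 1.4, 1.5, 2.7, 3.3, 3.3, 4.1,
               2.2, 1.5, 1.5)
    ),
    NK_cells = list(
      .profile(4.55, 4.50, 3.90, 1.5, 1.3, 1.4, 1.4, 3.1, 3.0, 4.3,
               1.5, 1.3, 1.3)
    ),
    plasma_cells = list(
      .profile(4.60, 4.55, 3.80, 1.5, 2.9, 1.6, 1.5, 4.7, 2.8, 2.9,
               3.2, 1.6, 1.6)
    ),
    T_cells = list(
      .profile(4.55, 4.50, 3.70, 3.8, 1.3, 1.4, 1.3, 2.4, 3.7, 4.4,
               1.8, 1.3, 1.3)
    ),
    unknown = list(
      .profile(4.30, 4.25, 3.90, 2.2, 2.2, 2.2, 2.2, 2.2, 2.2, 2.2,
               2.2, 2.2, 2.2, sd = 0.55, scatter_sd = 0.20)
    )
  )
  # hematogone CD20 is a maturation continuum: widen that channel
  profiles$hematogones[[1]]$sd["CD20-APC-H7"] <- 0.35
  profiles[cll_classes()]
}

#' Default spectral-overlap (spillover) matrix
#'
#' A fixed 10 x 10 mixing matrix over the fluorescence channels: unit
#' diagonal, non-negative off-diagonal spill between spectrally adjacent
#' dyes. The matrix is diagonally dominant and nonsingular, so the
#' uncompensated representation the classifier consumes carries the same
#' class-separation information as the compensated one.
#'
#' @return 10 x 10 numeric matrix; entry `[i, j]` is the fraction of dye
#'   `i` signal detected in channel `j`.
#' @export
default_spillover <- function() {
  fl <- cll_panel()$name[4:13]
  s <- diag(10)
  dimnames(s) <- list(fl, fl)
  spill <- rbind(
    # emitter,            detector,            fraction
    c("CD200-BV421",      "CD5-BV480",         0.12),
    c("CD5-BV480",        "CD200-BV421",       0.06),
    c("CD5-BV480",        "CD43-BV605",        0.05),
    c("CD43-BV605",       "CD5-BV480",         0.03),
    c("Kappa-FITC",       "Lambda-PE",         0.10),
    c("Kappa-FITC",       "CD45-PerCP-Cy5.5",  0.02),
    c("Lambda-PE",        "CD45-PerCP-Cy5.5",  0.08),
    c("Lambda-PE",        "Kappa-FITC",        0.03),
    c("CD45-PerCP-Cy5.5", "CD19-PE-Cy7",       0.06),
    c("CD19-PE-Cy7",      "CD45-PerCP-Cy5.5",  0.03),
    c("CD22-APC",         "CD38-APC-R700",     0.09),
    c("CD38-APC-R700",    "CD22-APC",          0.04),
    c("CD38-APC-R700",    "CD20-APC-H7",       0.07),
    c("CD20-APC-H7",      "CD38-APC-R700",     0.05),
    c("CD43-BV605",       "Lambda-PE",         0.04)
  )
  for (r in seq_len(nrow(spill))) {
    s[spill[r, 1], spill[r, 2]] <- as.numeric(spill[r, 3])
  }
  s
}

#' Configuration for one simulated case
#'
#' @param n_events Total events acquired for the tube (default 1.2e6, the
#'   full acquisition depth; scale down for quick experiments).
#' @param class_fractions Named non-negative fractions of total events per
#'   class, summing to at most 1; any remainder is assigned to debris.
#'   Defaults approximate a post-therapy specimen: CLL ~5% of events,
#'   T cells ~10%, aggregates 7%, debris 15%, granulocyte-dominated rest.
#' @param cll_fraction_of_wbc Optional target CLL fraction of WBC events
#'   (WBC = everything except aggregates and debris). When given, the CLL
#'   share of the WBC compartment is set to this value and the remaining
#'   WBC classes are rescaled proportionally.
#' @param atypical_cd20_bright Simulate the atypical CD20-bright CLL
#'   phenotype.
#' @param cll_lambda_restricted Mirror CLL light-chain restriction to
#'   lambda.
#' @param case_effect_sd Between-case biological variation: each class's
#'   per-channel log10 location is shifted once per case by
#'   `N(0, case_effect_sd)` on fluorescence channels (scatter shifts are
#'   40% of that). Patients' populations sit at patient-specific levels;
#'   0 disables the effect.
#' @param specimen Specimen type.
#' @param case_id Case identifier.
#' @param seed Integer RNG seed; the case is bit-reproducible given the
#'   seed.
#' @return A list of class `CaseConfig`.
#' @export
case_config <- function(n_events = 1.2e6,
                        class_fractions = default_class_fractions(),
                        cll_fraction_of_wbc = NULL,
                        atypical_cd20_bright = FALSE,
                        cll_lambda_restricted = FALSE,
                        case_effect_sd = 0,
                        specimen = "peripheral_blood",
                        case_id = "sim_case",
                        seed = 1L) {
  stopifnot(n_events >= 0, seed == as.integer(seed))
  fr <- class_fractions[cll_classes()]
  fr[is.na(fr)] <- 0
  names(fr) <- cll_classes()
  if (any(fr < 0)) stop("class fractions must be non-negative", call. = FALSE)
  if (sum(fr) > 1 + 1e-9) {
    stop("class fractions sum to ", round(sum(fr), 4), " > 1", call. = FALSE)
  }
  fr["debris"] <- fr["debris"] + max(0, 1 - sum(fr))
  if (!is.null(cll_fraction_of_wbc)) {
    stopifnot(cll_fraction_of_wbc >= 0, cll_fraction_of_wbc <= 1)
    wbc_classes <- setdiff(cll_classes(), c("aggregates", "debris"))
    wbc_share <- sum(fr[wbc_classes])
    other <- setdiff(wbc_classes, "CLL_cells")
    other_sum <- sum(fr[other])
    fr["CLL_cells"] <- cll_fraction_of_wbc * wbc_share
    fr[other] <- fr[other] / other_sum *
      (wbc_share - fr[["CLL_cells"]])
  }
  stopifnot(case_effect_sd >= 0)
  structure(
    list(n_events = as.integer(n_events), class_fractions = fr,
         cll_fraction_of_wbc = cll_fraction_of_wbc,
         atypical_cd20_bright = isTRUE(atypical_cd20_bright),
         cll_lambda_restricted = isTRUE(cll_lambda_restricted),
         case_effect_sd = case_effect_sd,
         specimen = specimen, case_id = case_id, seed = as.integer(seed)),
    class = "CaseConfig"
  )
}

#' @rdname case_config
#' @export
default_class_fractions <- function() {
  c(CLL_cells = 0.050, aggregates = 0.070, B_cells = 0.035,
    basophils_dendritic = 0.010, blasts = 0.010, debris = 0.150,
    erythroblasts = 0.020, granulocytes = 0.435, hematogones = 0.015,
    monocytes = 0.060, NK_cells = 0.020, plasma_cells = 0.005,
    T_cells = 0.100, unknown = 0.020)
}

# Aggregates are synthesized as physical cell-cell doublets: two singlet
# cells drawn from the WBC class mix (debris does not clump into the
# aggregate gate), fluorescence and side scatter summed in linear space,
# forward-scatter area near the sum but height near the larger member --
# the area/height mismatch doublet discrimination relies on.
.draw_aggregates <- function(n, profiles, fractions) {
  if (n == 0L) return(matrix(numeric(0), ncol = 13L))
  mix <- fractions[setdiff(names(fractions), c("aggregates", "debris"))]
  mix <- mix[mix > 0]
  members <- sample(names(mix), 2L * n, replace = TRUE,
                    prob = mix / sum(mix))
  counts <- table(factor(members, levels = names(mix)))
  pool <- do.call(rbind, lapply(names(mix), function(cl) {
    .draw_class(counts[[cl]], profiles[[cl]])
  }))
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  a <- pool[seq_len(n), , drop = FALSE]
  b <- pool[n + seq_len(n), , drop = FALSE]
  out <- a + b
  out[, 1] <- 0.95 * (a[, 1] + b[, 1])          # FSC-A: near the sum
  out[, 2] <- 1.05 * pmax(a[, 2], b[, 2])       # FSC-H: larger member
  out
}

# Draw n log10-lognormal events from a (possibly mixture) profile.
.draw_class <- function(n, profile) {
  if (n == 0L) return(matrix(numeric(0), ncol = 13L))
  w <- vapply(profile, `[[`, numeric(1), "weight")
  comp <- sample.int(length(profile), n, replace = TRUE, prob = w)
  out <- matrix(0, n, 13L)
  for (k in seq_along(profile)) {
    idx <- which(comp == k)
    if (!length(idx)) next
    loc <- profile[[k]]$loc
    sdv <- profile[[k]]$sd
    z <- matrix(stats::rnorm(length(idx) * 13L), ncol = 13L)
    out[idx, ] <- 10^(sweep(sweep(z, 2, sdv, `*`), 2, loc, `+`))
  }
  out
}

#' Simulate one labeled case
#'
#' Per-class event counts are drawn from a multinomial over the configured
#' class fractions; intensities are lognormal per channel and class, with
#' aggregates synthesized as doublets (linear sums of two singlet events,
#' forward-scatter height staying near the larger member); the ten
#' fluorescence channels are then mixed through the spillover matrix (the
#' data stay uncompensated); events are shuffled into a random acquisition
#' order with truth labels attached. Bit-reproducible for a fixed seed.
#'
#' @param cfg A [case_config()].
#' @param spillover Spillover matrix, default [default_spillover()].
#' @return A [case_sample()] with truth labels;
#'   `true_cll_fraction` records the realized CLL fraction of WBC events.
#' @export
simulate_case <- function(cfg, spillover = default_spillover()) {
  stopifnot(inherits(cfg, "CaseConfig"))
  profiles <- default_profiles(
    atypical_cd20_bright = cfg$atypical_cd20_bright,
    cll_lambda_restricted = cfg$cll_lambda_restricted
  )
  set.seed(cfg$seed)
  classes <- cll_classes()
  if (cfg$case_effect_sd > 0) {
    # patient-specific population levels: one location shift per class
    shift_sd <- c(rep(0.4 * cfg$case_effect_sd, 3L),
                  rep(cfg$case_effect_sd, 10L))
    profiles <- lapply(profiles, function(prof) {
      shift <- stats::rnorm(13L, 0, shift_sd)
      lapply(prof, function(comp) {
        comp$loc <- comp$loc + shift
        comp
      })
    })
  }
  counts <- as.vector(stats::rmultinom(1, cfg$n_events,
                                       cfg$class_fractions[classes]))
  names(counts) <- classes
  blocks <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    blocks[[i]] <- if (classes[i] == "aggregates") {
      .draw_aggregates(counts[i], profiles, cfg$class_fractions)
    } else {
      .draw_class(counts[i], profiles[[classes[i]]])
    }
  }
  values <- do.call(rbind, blocks)
  labels <- rep(classes, counts)
  if (nrow(values) > 0L) {
    # uncompensated detection: mix true dye signals through spillover
    values[, 4:13] <- values[, 4:13] %*% spillover
    ord <- sample.int(nrow(values))
    values <- values[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  wbc <- sum(counts) - counts["aggregates"] - counts["debris"]
  case_sample(
    event_matrix(values),
    truth = labels,
    case_id = cfg$case_id,
    specimen = cfg$specimen,
    true_cll_fraction = if (wbc > 0) unname(counts["CLL_cells"] / wbc)
                        else NA_real_
  )
}

#' Spike-in dilution plan
#'
#' @param donor_case Labeled [case_sample()] with CLL events (the
#'   high-burden donor).
#' @param background_case Labeled CLL-free [case_sample()] (normal
#'   peripheral blood or bone marrow).
#' @param target_fractions Targeted clonal percentages of WBC events, as
#'   fractions; defaults to 0.02%, 0.002% and 0.001%.
#' @param replicates Replicates per dilution level.
#' @param seed Integer seed for the spiking draws.
#' @return A list of class `DilutionPlan`.
#' @export
dilution_plan <- function(donor_case, background_case,
                          target_fractions = c(2e-4, 2e-5, 1e-5),
                          replicates = 1L, seed = 1L) {
  stopifnot(inherits(donor_case, "CaseSample"),
            inherits(background_case, "CaseSample"))
  if (is.null(donor_case$truth) ||
      !any(donor_case$truth == "CLL_cells")) {
    stop("donor case has no CLL truth events to spike", call. = FALSE)
  }
  if (is.null(background_case$truth)) {
    stop("background case needs truth labels", call. = FALSE)
  }
  if (any(background_case$truth == "CLL_cells")) {
    stop("background case must be CLL-free", call. = FALSE)
  }
  if (any(target_fractions <= 0 | target_fractions >= 1)) {
    stop("target fractions must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(donor_case = donor_case, background_case = background_case,
         target_fractions = target_fractions,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "DilutionPlan"
  )
}

#' Generate a spike-in serial dilution series
#'
#' For every target fraction and replicate, the number of spiked events is
#' drawn binomially over the background case's WBC denominator with
#' success probability `f / (1 - f)` — spiked events join the denominator,
#' so this makes the realized CLL fraction of final WBC unbiased for the
#' target `f`. That many donor CLL events
#' are resampled (with replacement) and mixed into the background case at
#' random positions, truth labels carried over.
#'
#' @param plan A [dilution_plan()].
#' @return List of [case_sample()]s, one per (fraction, replicate), with
#'   `true_cll_fraction` set to the realized fraction. Case ids encode
#'   donor, level and replicate.
#' @export
spike_dilution <- function(plan) {
  stopifnot(inherits(plan, "DilutionPlan"))
  set.seed(plan$seed)
  bg <- plan$background_case
  donor_idx <- which(plan$donor_case$truth == "CLL_cells")
  donor_ev <- unclass(plan$donor_case$events)[donor_idx, , drop = FALSE]
  wbc_bg <- sum(!bg$truth %in% c("aggregates", "debris"))
  out <- list()
  for (f in plan$target_fractions) {
    for (r in seq_len(plan$replicates)) {
      k <- stats::rbinom(1, wbc_bg, f / (1 - f))
      spike <- donor_ev[sample.int(nrow(donor_ev), k, replace = TRUE), ,
                        drop = FALSE]
      values <- rbind(unclass(bg$events), spike)
      labels <- c(bg$truth, rep("CLL_cells", k))
      ord <- sample.int(length(labels))
      cid <- sprintf("%s_sp%g_r%d", plan$donor_case$case_id, f, r)
      out[[cid]] <- case_sample(
        event_matrix(values[ord, , drop = FALSE],
                     channels = colnames(bg$events)),
        truth = labels[ord], case_id = cid, specimen = bg$specimen,
        true_cll_fraction = k / (wbc_bg + k)
      )
    }
  }
  out
}

#' Simulate a labeled development cohort
#'
#' Mixes MRD-negative cases (no CLL events), high-burden MRD-positive
#' cases (CLL well above 1000 events) and low-count MRD-positive cases
#' (CLL truth count targeted between 40 and 800 events, i.e. below the
#' 1000-event low-count threshold). The atypical CD20-bright phenotype is
#' assigned only to a fraction of the high-burden cases, mirroring how an
#' unusual phenotype enters a real cohort through high-count specimens
#' and is therefore absent from the low-count training subset.
#'
#' Per-case seeds are `seed + case index`, so any single case can be
#' regenerated in isolation.
#'
#' @param n_cases Number of cases (>= 1).
#' @param mrd_positive_fraction Fraction of MRD-positive cases (default
#'   143/202, the development-cohort mix).
#' @param low_count_fraction Fraction of the positive cases that are
#'   low-count (< 1000 CLL events).
#' @param n_events Events per case.
#' @param atypical_fraction Fraction of high-burden positive cases given
#'   the atypical CD20-bright phenotype.
#' @param seed Master integer seed.
#' @return List of [case_sample()]s with a `manifest` attribute (a data
#'   frame of case_id, specimen, true status, true CLL count, WBC count,
#'   events, atypical flag and per-case seed).
#' @export
make_cohort <- function(n_cases, mrd_positive_fraction = 143 / 202,
                        low_count_fraction = 0.55, n_events = 1.2e6,
                        atypical_fraction = 0.25, seed = 1L) {
  if (n_cases < 1) stop("n_cases must be >= 1", call. = FALSE)
  stopifnot(mrd_positive_fraction >= 0, mrd_positive_fraction <= 1,
            low_count_fraction >= 0, low_count_fraction <= 1)
  n_pos <- round(n_cases * mrd_positive_fraction)
  n_low <- round(n_pos * low_count_fraction)
  n_high <- n_pos - n_low
  n_atyp <- round(n_high * atypical_fraction)
  wbc_expect <- 0.78 * n_events  # WBC share of default class fractions

  roles <- c(rep("negative", n_cases - n_pos),
             rep("low", n_low), rep("high", n_high))
  atypical <- c(rep(FALSE, n_cases - n_pos + n_low),
                rep(c(TRUE, FALSE), c(n_atyp, n_high - n_atyp)))
  set.seed(seed)
  roles_ord <- sample.int(n_cases)
  roles <- roles[roles_ord]; atypical <- atypical[roles_ord]
  specimen <- sample(c("peripheral_blood", "bone_marrow"), n_cases,
                     replace = TRUE, prob = c(0.7, 0.3))
  # case-level draws fixed up front so each case depends only on its seed
  low_targets <- 10^stats::runif(n_cases, log10(30), log10(400))
  high_fracs <- 10^stats::runif(n_cases, log10(0.05), log10(0.6))

  cohort <- vector("list", n_cases)
  manifest <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    frac <- switch(roles[i],
      negative = 0,
      low = min(low_targets[i] / wbc_expect, 1),
      high = min(max(high_fracs[i], 2000 / wbc_expect), 0.95)
    )
    cid <- sprintf("case_%03d", i)
    cfg <- case_config(
      n_events = n_events, cll_fraction_of_wbc = frac,
      atypical_cd20_bright = atypical[i], specimen = specimen[i],
      case_id = cid, seed = seed + i
    )
    cs <- simulate_case(cfg)
    cohort[[i]] <- cs
    manifest[[i]] <- data.frame(
      case_id = cid, specimen = specimen[i], role = roles[i],
      true_status = if (sum(cs$truth == "CLL_cells") >= 20) "MRD_positive"
                    else "MRD_negative",
      true_cll_count = sum(cs$truth == "CLL_cells"),
      wbc_count = sum(!cs$truth %in% c("aggregates", "debris")),
      n_events = nrow(cs$events), atypical = atypical[i],
      seed = seed + i, stringsAsFactors = FALSE
    )
  }
  names(cohort) <- vapply(cohort, `[[`, character(1), "case_id")
  attr(cohort, "manifest") <- do.call(rbind, manifest)
  cohort
}

#' @rdname make_cohort
#' @param cohort A cohort list produced by `make_cohort()`.
#' @return `cohort_manifest`: the manifest data frame.
#' @export
cohort_manifest <- function(cohort) {
  m <- attr(cohort, "manifest")
  if (is.null(m)) stop("cohort carries no manifest", call. = FALSE)
  m
}
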