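# Shared fixtures: all synthetic, generated in code at test time.

# Small labeled case for I/O and workflow tests.
tiny_case <- function(n = 500, cll_frac = 0.05, seed = 42,
                      case_id = "tiny") {
  simulate_case(case_config(n_events = n, cll_fraction_of_wbc = cll_frac,
                            case_id = case_id, seed = seed))
}

# A TrainedModel whose output is a constant class, for cascade-logic tests.
constant_model <- function(class, tag = "F") {
  classes <- cll_classes()
  spec <- network_spec()
  sizes <- c(spec$input_dim, spec$hidden, spec$output_dim)
  W <- lapply(seq_len(length(sizes) - 1L),
              function(l) matrix(0, sizes[l], sizes[l + 1L]))
  b <- lapply(sizes[-1], function(s) rep(0, s))
  b[[length(b)]][match(class, classes)] <- 50
  structure(
    list(weights = W, biases = b, spec = spec, scale = rep(1, 13),
         classes = classes, loss_history = 0.05, val_history = numeric(0),
         epochs_run = 1L, target_reached = TRUE, cohort_tag = tag,
         seed = 1L, version = 1L),
    class = "TrainedModel"
  )
}

# A TrainedModel that calls CLL_cells when FSC-A exceeds `threshold`,
# debris otherwise: lets tests place the F-DNN CLL count exactly.
gate_model <- function(threshold = 0.5, tag = "F") {
  m <- constant_model("debris", tag)
  # single positive path through the net carrying FSC-A
  m$weights[[1]][1, 1] <- 1
  m$weights[[2]][1, 1] <- 1
  m$weights[[3]][1, 1] <- 1
  m$weights[[4]][1, match("CLL_cells", m$classes)] <- 1
  m$biases[[4]][match("debris", m$classes)] <- threshold
  m$biases[[4]][match("CLL_cells", m$classes)] <- 0
  m
}

# Events whose FSC-A column is `x1` and all other channels 0.1.
gate_events <- function(x1) {
  v <- matrix(0.1, length(x1), 13)
  v[, 1] <- x1
  event_matrix(v)
}

# Shared trained F-DNN / L-DNN pair, trained once per test run on a
# 20-case development cohort (15k events/case) and memoized.
.shared_env <- new.env(parent = emptyenv())
shared_models <- function() {
  if (!is.null(.shared_env$models)) return(.shared_env$models)
  cohort <- make_cohort(20, n_events = 15000, seed = 101)
  spec <- network_spec(max_epochs = 200)
  split <- split_spec(seed = 7)
  f <- train_f_dnn(cohort, spec, split, seed = 5)
  l <- train_l_dnn(cohort, spec, split, seed = 5)
  .shared_env$models <- list(cohort = cohort, split = split, f = f, l = l)
  .shared_env$models
}
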