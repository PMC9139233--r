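# Event-level deep neural network: 13 input channels, three fully
# connected hidden layers (64, 128, 64), 14-class softmax output,
# categorical cross-entropy, Adam. Trained in its F-DNN (full cohort) and
# L-DNN (low-count cohort) instantiations.

#' Network architecture and training hyperparameters
#'
#' The architecture is fixed by design: 13 inputs, hidden layers of 64,
#' 128 and 64 rectified-linear nodes, a 14-class softmax output, no
#' dropout. Training stops when the epoch training loss (categorical
#' cross-entropy) drops below `cost_target`, or at `max_epochs`.
#'
#' @param input_dim,hidden,output_dim Layer sizes.
#' @param cost_target Stop when epoch training loss falls below this
#'   (default 0.08).
#' @param max_epochs Epoch cap (default 3000).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters
#'   (library defaults).
#' @param batch_size Mini-batch size (default 4096).
#' @return A list of class `NetworkSpec`.
#' @export
network_spec <- function(input_dim = 13L, hidden = c(64L, 128L, 64L),
                         output_dim = 14L, cost_target = 0.08,
                         max_epochs = 3000L, learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         batch_size = 4096L) {
  stopifnot(cost_target > 0, max_epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(
    list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
         output_dim = as.integer(output_dim), cost_target = cost_target,
         max_epochs = as.integer(max_epochs),
         learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         epsilon = epsilon, batch_size = as.integer(batch_size)),
    class = "NetworkSpec"
  )
}

#' Event-level train/validation/test split specification
#'
#' Splitting is by event, not by case: every event in the pooled cohort is
#' assigned to exactly one partition as a function of the seed, in an
#' 80:10:10 ratio by default. (Events from one case can therefore appear
#' in both train and test pools; this mirrors the training design and is a
#' documented caveat, not an accident.)
#'
#' @param train,validation,test Fractions summing to 1.
#' @param seed Integer seed controlling the assignment.
#' @return A list of class `SplitSpec`.
#' @export
split_spec <- function(train = 0.8, validation = 0.1, test = 0.1,
                       seed = 1L) {
  if (abs(train + validation + test - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  structure(list(train = train, validation = validation, test = test,
                 seed = as.integer(seed)),
            class = "SplitSpec")
}

#' Partition cohort events into train/validation/test pools
#'
#' Pools are disjoint and cover every event exactly once; counts follow
#' floor rounding (train and validation floored, remainder to test).
#' Each pool retains per-event provenance (case id and within-case event
#' index) so case-level results can be reassembled from test events.
#'
#' @param cohort List of labeled [case_sample()]s.
#' @param spec A [split_spec()].
#' @return List with elements `train`, `validation`, `test`; each is a
#'   list of `x` (event matrix), `y` (labels) and `provenance`
#'   (data frame `case_id`, `event_index`).
#' @export
split_events <- function(cohort, spec = split_spec()) {
  stopifnot(inherits(spec, "SplitSpec"))
  unlabeled <- vapply(cohort, function(cs) is.null(cs$truth), logical(1))
  if (any(unlabeled)) {
    stop("all cases must carry truth labels; missing for: ",
         paste(vapply(cohort[unlabeled], `[[`, character(1), "case_id"),
               collapse = ", "), call. = FALSE)
  }
  x <- do.call(rbind, lapply(cohort, function(cs) unclass(cs$events)))
  y <- unlist(lapply(cohort, `[[`, "truth"), use.names = FALSE)
  prov <- do.call(rbind, lapply(cohort, function(cs) {
    data.frame(case_id = rep(cs$case_id, nrow(cs$events)),
               event_index = seq_len(nrow(cs$events)),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(x)
  n_train <- floor(spec$train * n)
  n_val <- floor(spec$validation * n)
  set.seed(spec$seed)
  ord <- sample.int(n)
  idx <- list(train = ord[seq_len(n_train)],
              validation = ord[n_train + seq_len(n_val)],
              test = ord[setdiff(seq_len(n), seq_len(n_train + n_val))])
  lapply(idx, function(i) {
    list(x = x[i, , drop = FALSE], y = y[i],
         provenance = prov[i, , drop = FALSE])
  })
}

# He-initialized weights/biases for the given layer sizes, drawn from R's
# RNG so initialization is reproducible under set.seed().
.init_weights <- function(sizes) {
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L],
                                  sd = sqrt(2 / fan_in)),
                     nrow = fan_in)
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

#' Train the event classifier
#'
#' Raw, uncompensated intensities are fed to the network after a fixed
#' per-channel affine rescale (division by the training pool's per-channel
#' maximum); the constants are stored in the model and reused at
#' inference, so the semantics stay "raw" while optimization is
#' conditioned. Training iterates Adam mini-batch epochs until the epoch
#' training loss falls below `spec$cost_target` or `spec$max_epochs` is
#' reached; in the latter case the model is returned with
#' `target_reached = FALSE` and a warning. Deterministic for a fixed seed
#' and thread count (a multithreaded BLAS can introduce rounding-level
#' differences).
#'
#' @param train Training pool (list with `x`, `y`) from [split_events()].
#' @param validation Optional validation pool; its loss is tracked per
#'   epoch and reported alongside, but does not drive stopping.
#' @param spec A [network_spec()].
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param cohort_tag `"F"`, `"L"` or other tag recording the training
#'   cohort.
#' @return A list of class `TrainedModel`: weights, biases, scaling
#'   constants, class ontology, per-epoch `loss_history` (and
#'   `val_history`), `epochs_run`, `target_reached`, `cohort_tag`, `seed`.
#' @export
train_dnn <- function(train, validation = NULL, spec = network_spec(),
                      seed = 1L, cohort_tag = "F") {
  stopifnot(inherits(spec, "NetworkSpec"))
  if (length(train$y) == 0L) stop("training pool is empty", call. = FALSE)
  classes <- cll_classes()
  y <- match(validate_labels(train$y), classes) - 1L
  scale <- apply(train$x, 2, max)
  scale[scale <= 0] <- 1
  xs <- sweep(train$x, 2, scale, "/")
  if (!is.null(validation) && length(validation$y) > 0L) {
    xv <- sweep(validation$x, 2, scale, "/")
    yv <- match(validate_labels(validation$y), classes) - 1L
  } else {
    xv <- matrix(numeric(0), ncol = ncol(xs))
    yv <- integer(0)
  }
  set.seed(seed)
  init <- .init_weights(c(spec$input_dim, spec$hidden, spec$output_dim))
  fit <- cpp_mlp_train(xs, y, xv, yv, init$W, init$b,
                       spec$learning_rate, spec$beta1, spec$beta2,
                       spec$epsilon, spec$batch_size, spec$max_epochs,
                       spec$cost_target, as.integer(seed))
  if (!fit$target_reached) {
    warning("cost target ", spec$cost_target, " not reached in ",
            fit$epochs_run, " epochs (final loss ",
            signif(utils::tail(fit$loss_history, 1), 4), ")",
            call. = FALSE)
  }
  structure(
    list(weights = fit$weights, biases = fit$biases, spec = spec,
         scale = scale, classes = classes,
         loss_history = as.numeric(fit$loss_history),
         val_history = as.numeric(fit$val_history),
         epochs_run = fit$epochs_run,
         target_reached = fit$target_reached,
         cohort_tag = cohort_tag, seed = as.integer(seed),
         version = 1L),
    class = "TrainedModel"
  )
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat("TrainedModel (", x$cohort_tag, "-DNN): ",
      paste(c(x$spec$input_dim, x$spec$hidden, x$spec$output_dim),
            collapse = "-"), "\n", sep = "")
  cat("  epochs:", x$epochs_run, " final loss:",
      signif(utils::tail(x$loss_history, 1), 4),
      if (x$target_reached) "(target reached)" else "(target NOT reached)",
      "\n")
  invisible(x)
}

#' Train the full-cohort (F-DNN) and low-count (L-DNN) networks
#'
#' `train_f_dnn` trains on every case in the cohort. `train_l_dnn` trains
#' only on cases whose truth CLL event count is below
#' `low_count_threshold` (1000 events); MRD-negative cases qualify, since
#' zero is below the threshold. Both share the same split and training
#' machinery.
#'
#' @param cohort List of labeled [case_sample()]s.
#' @param spec A [network_spec()].
#' @param split A [split_spec()].
#' @param seed Training seed (initialization + shuffling).
#' @param low_count_threshold CLL truth-count cutoff defining the L
#'   cohort.
#' @return A `TrainedModel` (see [train_dnn()]).
#' @export
train_f_dnn <- function(cohort, spec = network_spec(),
                        split = split_spec(), seed = 1L) {
  pools <- split_events(cohort, split)
  train_dnn(pools$train, pools$validation, spec, seed, cohort_tag = "F")
}

#' @rdname train_f_dnn
#' @export
train_l_dnn <- function(cohort, spec = network_spec(),
                        split = split_spec(), seed = 1L,
                        low_count_threshold = 1000L) {
  keep <- vapply(cohort, function(cs) {
    if (is.null(cs$truth)) stop("all cases must carry truth labels",
                                call. = FALSE)
    sum(cs$truth == "CLL_cells") < low_count_threshold
  }, logical(1))
  if (!any(keep)) {
    stop("low-count cohort is empty: no case has < ", low_count_threshold,
         " CLL truth events", call. = FALSE)
  }
  pools <- split_events(cohort[keep], split)
  train_dnn(pools$train, pools$validation, spec, seed, cohort_tag = "L")
}

#' Classify events with a trained model
#'
#' Applies the stored per-channel rescale, runs the network, and returns
#' per-event class probabilities (a simplex per event) plus argmax labels.
#' Batch order does not affect outputs; argmax ties break to the lowest
#' class index in ontology order.
#'
#' @param model A `TrainedModel`.
#' @param events An [event_matrix()] (or a `CaseSample`, whose events are
#'   used).
#' @return List with `probabilities` (N x 14 matrix, columns named by
#'   class) and `labels` (character vector of predicted classes).
#' @export
predict_events <- function(model, events) {
  stopifnot(inherits(model, "TrainedModel"))
  if (inherits(events, "CaseSample")) events <- events$events
  x <- unclass(events)
  if (ncol(x) != model$spec$input_dim) {
    stop("panel mismatch: model expects ", model$spec$input_dim,
         " channels, events have ", ncol(x), call. = FALSE)
  }
  if (nrow(x) == 0L) {
    p <- matrix(numeric(0), ncol = length(model$classes))
    colnames(p) <- model$classes
    return(list(probabilities = p, labels = character(0)))
  }
  xs <- sweep(x, 2, model$scale, "/")
  p <- cpp_mlp_predict(model$weights, model$biases, xs,
                       model$spec$batch_size)
  colnames(p) <- model$classes
  labels <- model$classes[max.col(p, ties.method = "first")]
  list(probabilities = p, labels = labels)
}

#' Save or load a model checkpoint
#'
#' Checkpoints carry the weights, network spec, scaling constants, seed
#' and ontology order, plus a format version.
#'
#' @param model A `TrainedModel`.
#' @param path Checkpoint file path.
#' @return `load_model`: the restored `TrainedModel`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "TrainedModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "TrainedModel")) {
    stop("not a model checkpoint: ", path, call. = FALSE)
  }
  model
}
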