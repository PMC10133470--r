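#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-5,
#' batch size 16, dropout handled by the model config, and early stop when
#' the epoch-mean training loss falls below 0.15. `max_epochs` is a safety
#' guard for data on which the loss threshold never triggers.
#'
#' @param learning_rate Adam step size (default 1e-5).
#' @param batch_size Mini-batch size (default 16).
#' @param loss_stop_threshold Stop when epoch-mean training loss drops below
#'   this value (default 0.15).
#' @param max_epochs Hard cap on epochs (default 200).
#' @param seed Integer seed controlling initialization, data order and
#'   dropout.
#' @param standardize Z-score features using statistics of the training set
#'   (default TRUE).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 16L,
                         loss_stop_threshold = 0.15, max_epochs = 200L,
                         seed = 1L, standardize = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 1, loss_stop_threshold > 0, max_epochs >= 0)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 loss_stop_threshold = loss_stop_threshold,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "train_config")
}

#' Fast training profile
#'
#' A profile for desk-scale experiments and continuous testing: larger
#' learning rate and batch, fewer epochs, same stopping rule.
#' @param seed Integer seed.
#' @return A [train_config()].
#' @export
train_config_test <- function(seed = 1L) {
  train_config(learning_rate = 1e-3, batch_size = 32L, loss_stop_threshold = 0.15,
               max_epochs = 40L, seed = seed)
}

# ---- dataset assembly ------------------------------------------------------

#' Assemble model-ready samples from feature tensors
#'
#' Groups each trial's windows into non-overlapping sequences of `t_in`
#' consecutive windows (incomplete trailing groups discarded), yielding the
#' `B x N x F x T` sample arrays consumed by the network.
#'
#' @param tensors List of `feature_tensor` objects.
#' @param t_in Windows per sample (default 10).
#' @return List with `x` (`S x N x F x T` array), `y` (integer labels),
#'   `subject` (character), `trial` (character).
#' @export
build_samples <- function(tensors, t_in = 10L) {
  stopifnot(length(tensors) > 0)
  xs <- list(); ys <- integer(0); subj <- character(0); tri <- character(0)
  for (ft in tensors) {
    v <- ft$values                        # T x N x F
    nwin <- dim(v)[1]
    ngrp <- nwin %/% t_in
    if (ngrp < 1L) next
    for (g in seq_len(ngrp)) {
      rows <- ((g - 1L) * t_in + 1L):(g * t_in)
      xs[[length(xs) + 1L]] <- aperm(v[rows, , , drop = FALSE], c(2L, 3L, 1L))  # N x F x T
      ys <- c(ys, ft$label)
      subj <- c(subj, ft$subject_id)
      tri <- c(tri, ft$trial_id)
    }
  }
  if (!length(xs)) stop_config("no trial provided at least %d windows", t_in)
  N <- dim(xs[[1]])[1]; F <- dim(xs[[1]])[2]; T <- dim(xs[[1]])[3]
  x <- array(0, c(length(xs), N, F, T))
  for (i in seq_along(xs)) x[i, , , ] <- xs[[i]]
  list(x = x, y = ys, subject = subj, trial = tri)
}

fit_standardizer <- function(x) {
  # per (channel, band) statistics over samples and time
  d <- dim(x)
  m <- apply(x, c(2L, 3L), mean)
  s <- apply(x, c(2L, 3L), stats::sd)
  s[s < 1e-8] <- 1
  list(mean = m, sd = s)
}

apply_standardizer <- function(x, st) {
  d <- dim(x)
  mrep <- aperm(array(st$mean, c(d[2], d[3], d[1], d[4])), c(3L, 1L, 2L, 4L))
  srep <- aperm(array(st$sd, c(d[2], d[3], d[1], d[4])), c(3L, 1L, 2L, 4L))
  (x - mrep) / srep
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] - lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- train / evaluate ------------------------------------------------------

#' Train a model
#'
#' Mini-batch cross-entropy training with Adam. Stops when the epoch-mean
#' training loss drops below `tcfg$loss_stop_threshold` or after
#' `tcfg$max_epochs`. Fully seeded: initialization, shuffling and dropout
#' derive from `tcfg$seed`.
#'
#' @param train_set List with `x` (`S x N x F x T`) and `y` (integer labels
#'   in `1..n_classes`), e.g. from [build_samples()].
#' @param cfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param static_A Optional static adjacency for `tgat` variants; computed
#'   from `montage` when needed and missing.
#' @param montage Optional [electrode_montage()] used to build the static
#'   kNN graph.
#' @param verbose Print per-epoch loss.
#' @return A `stgate_model`: list with `params`, `state`, `config`,
#'   `static_A`, `standardizer`, `history` (per-epoch mean loss).
#' @export
train <- function(train_set, cfg, tcfg = train_config(), static_A = NULL,
                  montage = NULL, verbose = FALSE) {
  x <- train_set$x; y <- train_set$y
  if (is.null(x) || !length(y)) stop_config("empty training set")
  if (any(y < 1L | y > cfg$n_classes)) stop_config("labels out of range 1..%d", cfg$n_classes)
  if (cfg$has_tgat && !cfg$has_sgat && is.null(static_A)) {
    if (is.null(montage)) stop_config("variant '%s' needs static_A or a montage", cfg$variant)
    static_A <- knn_graph(montage$coords2d, min(cfg$k_nn, cfg$n_channels - 1L))
  }
  set.seed(tcfg$seed)
  mod <- init_model(cfg)
  st <- NULL
  if (tcfg$standardize) {
    st <- fit_standardizer(x)
    x <- apply_standardizer(x, st)
  }
  params <- mod$params; state <- mod$state
  opt <- adam_init(params)
  S <- dim(x)[1]
  history <- numeric(0)
  if (tcfg$max_epochs > 0L) {
    for (epoch in seq_len(tcfg$max_epochs)) {
      ord <- sample.int(S)
      nb <- ceiling(S / tcfg$batch_size)
      tot <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * tcfg$batch_size + 1L):min(b * tcfg$batch_size, S)]
        xb <- x[idx, , , , drop = FALSE]
        fw <- network_fwd(xb, params, cfg, state, train = TRUE, static_A = static_A)
        state <- fw$state
        ce <- cross_entropy(fw$logits, y[idx])
        tot <- tot + ce$loss * length(idx)
        grads <- network_bwd(fw, params, cfg, ce$dlogits)
        stp <- adam_step(params, grads, opt, tcfg$learning_rate)
        params <- stp$params; opt <- stp$opt
      }
      history <- c(history, tot / S)
      if (verbose) message(sprintf("epoch %3d  loss %.4f", epoch, tot / S))
      if (tot / S < tcfg$loss_stop_threshold) break
    }
  }
  structure(list(params = params, state = state, config = cfg,
                 static_A = static_A, standardizer = st, history = history),
            class = "stgate_model")
}

#' Evaluate a trained model
#'
#' Argmax-of-logits classification in evaluation mode.
#'
#' @param model A `stgate_model` from [train()].
#' @param test_set List with `x` and `y` as in [train()].
#' @param batch_size Forward-pass batch size.
#' @return List with `accuracy`, `confusion` (rows = true class) and
#'   `predictions`.
#' @export
evaluate <- function(model, test_set, batch_size = 32L) {
  x <- test_set$x; y <- test_set$y
  if (is.null(x) || !length(y)) stop_config("empty test set")
  if (any(y < 1L | y > model$config$n_classes)) {
    stop_config("test labels out of range for a %d-class model", model$config$n_classes)
  }
  if (!is.null(model$standardizer)) x <- apply_standardizer(x, model$standardizer)
  S <- dim(x)[1]
  preds <- integer(S)
  for (b in seq_len(ceiling(S / batch_size))) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, S)
    fw <- network_fwd(x[idx, , , , drop = FALSE], model$params, model$config,
                      model$state, train = FALSE, static_A = model$static_A)
    preds[idx] <- max.col(fw$logits, ties.method = "first")
  }
  k <- model$config$n_classes
  confusion <- matrix(0L, k, k, dimnames = list(true = 1:k, pred = 1:k))
  for (i in seq_len(S)) confusion[y[i], preds[i]] <- confusion[y[i], preds[i]] + 1L
  list(accuracy = mean(preds == y), confusion = confusion, predictions = preds)
}

subset_samples <- function(set, keep) {
  list(x = set$x[keep, , , , drop = FALSE], y = set$y[keep],
       subject = set$subject[keep], trial = set$trial[keep])
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the fold's model trains on every other subject's
#' samples (feature standardization fitted on the training fold only) and is
#' tested on the held-out subject. Train/test subject disjointness is
#' asserted on every fold.
#'
#' @param samples Sample list from [build_samples()] (must carry `subject`).
#' @param cfg A [model_config()].
#' @param tcfg A [train_config()]; fold f trains with seed `tcfg$seed + f`.
#' @param montage Optional montage for static-adjacency variants.
#' @param verbose Print per-fold accuracy.
#' @return A `loso_result`: `per_subject` (named accuracies),
#'   `mean_accuracy`, `std_accuracy`, `confusions`.
#' @export
loso_cross_validation <- function(samples, cfg, tcfg = train_config(),
                                  montage = NULL, verbose = FALSE) {
  subjects <- sort(unique(samples$subject))
  if (length(subjects) < 2L) stop_config("LOSO needs at least 2 subjects")
  counts <- table(samples$subject)
  if (any(counts == 0)) stop_config("subject with zero trials")
  acc <- stats::setNames(numeric(length(subjects)), subjects)
  confusions <- vector("list", length(subjects)); names(confusions) <- subjects
  for (f in seq_along(subjects)) {
    s <- subjects[f]
    test_idx <- samples$subject == s
    train_set <- subset_samples(samples, !test_idx)
    test_set <- subset_samples(samples, test_idx)
    stopifnot(length(intersect(unique(train_set$subject), unique(test_set$subject))) == 0L)
    ftcfg <- tcfg; ftcfg$seed <- tcfg$seed + f
    model <- train(train_set, cfg, ftcfg, montage = montage)
    ev <- evaluate(model, test_set)
    acc[s] <- ev$accuracy
    confusions[[s]] <- ev$confusion
    if (verbose) message(sprintf("fold %s: accuracy %.3f", s, ev$accuracy))
  }
  structure(list(per_subject = acc, mean_accuracy = mean(acc),
                 std_accuracy = stats::sd(acc), confusions = confusions),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %d folds: mean accuracy %.3f (sd %.3f)\n",
              length(x$per_subject), x$mean_accuracy, x$std_accuracy))
  invisible(x)
}

#' Run the ablation grid
#'
#' One LOSO run per variant under identical seeds and fold assignments.
#'
#' @param samples Sample list from [build_samples()].
#' @param variants Character vector drawn from [variant_names()].
#' @param base_cfg A [model_config()] whose architecture fields are reused
#'   for every variant.
#' @param tcfg A [train_config()].
#' @param montage Montage for static-adjacency variants.
#' @param verbose Print progress.
#' @return Data frame: variant, mean, std, then one column per subject.
#' @export
ablation_suite <- function(samples, variants, base_cfg, tcfg = train_config(),
                           montage = NULL, verbose = FALSE) {
  bad <- setdiff(variants, variant_names())
  if (length(bad)) stop_config("unknown variant(s): %s", paste(bad, collapse = ", "))
  rows <- list()
  for (v in variants) {
    cfg <- base_cfg; cfg$variant <- v
    cfg$has_tlb <- v %in% c("tlb", "sgat_tlb", "tgat_tlb", "stgate")
    cfg$has_sgat <- v %in% c("sgat", "sgat_tlb", "stgat", "stgate")
    cfg$has_tgat <- v %in% c("tgat", "tgat_tlb", "stgat", "stgate")
    if (verbose) message("variant: ", v)
    res <- loso_cross_validation(samples, cfg, tcfg, montage = montage, verbose = verbose)
    row <- data.frame(variant = v, mean = res$mean_accuracy, std = res$std_accuracy,
                      stringsAsFactors = FALSE)
    for (s in names(res$per_subject)) row[[paste0("subject_", s)]] <- res$per_subject[[s]]
    rows[[v]] <- row
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
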