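#' Bundle observation sequences into an agent dataset
#'
#' @param xs list of numeric observation sequences (e.g. per-epoch GFP).
#' @param labels integer class labels (1..n_class) aligned with `xs`.
#' @param statics optional list of static feature vectors (equal lengths).
#' @param class_names optional class names.
#' @return An `agent_dataset`.
#' @export
agent_dataset <- function(xs, labels, statics = NULL, class_names = NULL) {
  stopifnot(length(xs) == length(labels))
  labels <- as.integer(labels)
  n_class <- max(labels)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_class))
  static_dim <- if (is.null(statics)) 0L else length(statics[[1]])
  examples <- lapply(seq_along(xs), function(i)
    list(x = as.numeric(xs[[i]]), label = labels[i],
         static = if (is.null(statics)) NULL else as.numeric(statics[[i]])))
  structure(list(examples = examples, n_class = n_class,
                 class_names = class_names, static_dim = static_dim),
            class = "agent_dataset")
}

#' @export
print.agent_dataset <- function(x, ...) {
  cat(sprintf("<agent_dataset> %d examples, %d classes (%s), static dim %d\n",
              length(x$examples), x$n_class,
              paste(x$class_names, collapse = ", "), x$static_dim))
  invisible(x)
}

dataset_slices <- function(dataset, idx) {
  ex <- dataset$examples[idx]
  list(xs = lapply(ex, `[[`, "x"),
       labels = vapply(ex, function(e) as.numeric(e$label), numeric(1)),
       statics = lapply(ex, `[[`, "static"))
}

# Stratified split indices.
stratified_split <- function(labels, train_fraction) {
  train_idx <- integer(0)
  for (cl in unique(labels)) {
    cl_idx <- sample(which(labels == cl))
    n_train <- max(1L, floor(train_fraction * length(cl_idx)))
    train_idx <- c(train_idx, cl_idx[seq_len(n_train)])
  }
  sort(train_idx)
}

# Build rl_episode objects from one sampled batch (training internals).
episodes_from_batch <- function(sl, out, cfg) {
  lapply(seq_along(sl$xs), function(i)
    structure(list(x = sl$xs[[i]], static = sl$statics[[i]],
                   label = sl$labels[i],
                   locations = out$locations[i, ], actions = out$actions[i, ],
                   rewards = out$rewards[i, ], returns = out$returns[i, ],
                   R = out$R[i], gamma = cfg$gamma,
                   probs = NULL, baselines = out$baselines[i, ],
                   masks = lapply(out$masks, function(m)
                     if (is.null(m)) NULL else m[i, , drop = FALSE]),
                   prediction = out$predictions[i]),
              class = "rl_episode"))
}

#' Train the glimpse agent by policy-gradient reinforcement learning
#'
#' Stratified train/validation split, epsilon-greedy trajectory sampling,
#' and one REINFORCE-with-baseline Adam update per batch. Training stops
#' early when the validation mean return has not improved for
#' `cfg$patience` epochs; the best-validation policy is returned.
#'
#' @param dataset an `agent_dataset` with at least 2 classes present.
#' @param cfg a `train_config`.
#' @param architecture `"cnn_gru_rl"`, `"cnn_rl"`, or `"gru_rl"`.
#' @param quiet suppress per-epoch progress messages.
#' @return An `rl_training`: `policy` (best by validation reward), `log`
#'   (per-epoch data frame), `train_idx`, `val_idx`, `architecture`.
#' @export
train <- function(dataset, cfg = train_config(),
                  architecture = c("cnn_gru_rl", "cnn_rl", "gru_rl"),
                  quiet = TRUE) {
  stopifnot(inherits(dataset, "agent_dataset"))
  architecture <- match.arg(architecture)
  labels <- vapply(dataset$examples, function(e) e$label, integer(1))
  if (length(unique(labels)) < 2)
    stop("training requires at least 2 classes present in the data")
  withr::with_seed(cfg$seed, {
    train_idx <- stratified_split(labels, cfg$train_fraction)
    val_idx <- setdiff(seq_along(labels), train_idx)
    policy <- agent_policy(dataset$n_class, architecture,
                           static_dim = dataset$static_dim, cfg = cfg,
                           seed = sample.int(1e8, 1L))
    val_sl <- dataset_slices(dataset, val_idx)
    val_statics <- statics_matrix(policy, val_sl$statics,
                                  length(val_sl$xs))
    episodes_seen <- 0L
    best_reward <- -Inf
    best_policy <- policy
    stall <- 0L
    log_rows <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      order_idx <- sample(train_idx)
      batch_starts <- seq(1L, length(order_idx), by = cfg$batch_size)
      ep_reward <- ep_acc <- 0
      n_seen <- 0L
      for (bs in batch_starts) {
        idx <- order_idx[bs:min(bs + cfg$batch_size - 1L,
                                length(order_idx))]
        sl <- dataset_slices(dataset, idx)
        statics <- statics_matrix(policy, sl$statics, length(idx))
        eps <- epsilon_at(cfg, episodes_seen)
        out <- run_batch(policy, sl$xs, statics, sl$labels, cfg,
                         epsilon = eps, stochastic = TRUE,
                         dropout = cfg$dropout)
        episodes <- episodes_from_batch(sl, out, cfg)
        upd <- reinforce_update(policy, episodes, cfg)
        policy <- upd$policy
        episodes_seen <- episodes_seen + length(idx)
        ep_reward <- ep_reward + sum(out$R)
        ep_acc <- ep_acc + sum(out$predictions == sl$labels)
        n_seen <- n_seen + length(idx)
      }
      val_out <- run_batch(policy, val_sl$xs, val_statics, val_sl$labels,
                           cfg, stochastic = FALSE, eval_mode = TRUE)
      val_reward <- mean(val_out$R)
      val_acc <- mean(val_out$predictions == val_sl$labels)
      log_rows[[ep]] <- data.frame(
        epoch = ep, epsilon = epsilon_at(cfg, episodes_seen),
        train_reward = ep_reward / n_seen, train_acc = ep_acc / n_seen,
        val_reward = val_reward, val_acc = val_acc)
      if (!quiet)
        message(sprintf("epoch %3d  train R %.3f acc %.3f | val R %.3f acc %.3f",
                        ep, ep_reward / n_seen, ep_acc / n_seen,
                        val_reward, val_acc))
      if (val_reward > best_reward + 1e-9) {
        best_reward <- val_reward
        best_policy <- policy
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    structure(list(policy = best_policy, final_policy = policy,
                   log = do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                         logical(1))]),
                   train_idx = train_idx, val_idx = val_idx,
                   architecture = architecture, cfg = cfg),
              class = "rl_training")
  })
}

#' @export
print.rl_training <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<rl_training> %s, %d epochs; final val acc %.3f, reward %.3f\n",
              x$architecture, nrow(x$log), last$val_acc, last$val_reward))
  invisible(x)
}

#' Per-class classification metrics from a contingency
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `PPV = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)`; undefined ratios (zero denominator) are reported as
#' `NA`, not 0.
#'
#' @param tp,fp,tn,fn contingency counts.
#' @return List with `acc`, `ppv`, `npv`.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(acc = div(tp + tn, tp + tn + fp + fn),
       ppv = div(tp, tp + fp),
       npv = div(tn, tn + fn))
}

#' Evaluate a policy on a labeled dataset
#'
#' Deterministic roll-out (mean locations, argmax actions); the final
#' step's action is the prediction. Reports the confusion matrix and
#' one-vs-rest ACC/PPV/NPV per class plus macro averages.
#'
#' @param policy an `agent_policy`.
#' @param dataset an `agent_dataset` (or subset of one).
#' @param cfg a `train_config` (glimpse count and discount).
#' @param idx optional example indices to evaluate on.
#' @return An `eval_report`.
#' @export
evaluate <- function(policy, dataset, cfg = train_config(), idx = NULL) {
  stopifnot(inherits(dataset, "agent_dataset"))
  if (length(dataset$examples) == 0) stop("empty dataset")
  idx <- idx %||% seq_along(dataset$examples)
  if (length(idx) == 0) stop("empty dataset")
  sl <- dataset_slices(dataset, idx)
  statics <- statics_matrix(policy, sl$statics, length(idx))
  out <- run_batch(policy, sl$xs, statics, sl$labels, cfg,
                   stochastic = FALSE, eval_mode = TRUE)
  k <- policy$n_class
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = dataset$class_names,
                                      predicted = dataset$class_names))
  for (i in seq_along(idx))
    confusion[sl$labels[i], out$predictions[i]] <-
      confusion[sl$labels[i], out$predictions[i]] + 1L
  per_class <- do.call(rbind, lapply(seq_len(k), function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[-cl, cl])
    fn <- sum(confusion[cl, -cl])
    tn <- sum(confusion) - tp - fp - fn
    m <- classification_metrics(tp, fp, tn, fn)
    data.frame(class = dataset$class_names[cl], tp = tp, fp = fp, tn = tn,
               fn = fn, acc = m$acc, ppv = m$ppv, npv = m$npv)
  }))
  structure(list(confusion = confusion, per_class = per_class,
                 accuracy = mean(out$predictions == sl$labels),
                 macro_acc = mean(per_class$acc, na.rm = TRUE),
                 macro_ppv = mean(per_class$ppv, na.rm = TRUE),
                 macro_npv = mean(per_class$npv, na.rm = TRUE),
                 mean_reward = mean(out$R), n = length(idx)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.3f\n", x$n, x$accuracy))
  print(x$confusion)
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Exact check of the policy-gradient estimator on an enumerable toy
#'
#' Builds a two-location / two-class, single-step decision problem whose
#' trajectories can be enumerated: a softmax location policy followed by a
#' location-conditional softmax action policy and an arbitrary reward
#' table. The REINFORCE-with-baseline estimator (the same advantage-
#' weighted log-probability gradient the agent update uses) is averaged
#' over all trajectories weighted by their probabilities and compared
#' against the central finite-difference gradient of the expected return.
#'
#' @param n_settings number of random parameter settings to check.
#' @param seed seed for the settings.
#' @param h finite-difference step.
#' @return Maximum relative error (sup-norm) across settings.
#' @export
pg_gradient_check <- function(n_settings = 3L, seed = 1L, h = 1e-5) {
  expected_return <- function(theta) {
    tl <- theta[1:2]; ta <- matrix(theta[3:6], 2, 2)
    pl <- as.numeric(softmax_rows(matrix(tl, 1)))
    j <- 0
    for (l in 1:2) {
      pa <- as.numeric(softmax_rows(matrix(ta[, l], 1)))
      for (a in 1:2) j <- j + pl[l] * pa[a] * rew[l, a]
    }
    j
  }
  worst <- 0
  for (s in seq_len(n_settings)) {
    env <- withr::with_seed(seed + s, list(
      theta = stats::rnorm(6, 0, 1),
      rew = matrix(stats::runif(4), 2, 2)))
    theta <- env$theta
    rew <- env$rew
    pl <- as.numeric(softmax_rows(matrix(theta[1:2], 1)))
    ta <- matrix(theta[3:6], 2, 2)
    baseline <- expected_return(theta)   # value baseline = E[R]
    est <- numeric(6)
    for (l in 1:2) {
      pa <- as.numeric(softmax_rows(matrix(ta[, l], 1)))
      glp_l <- as.numeric(softmax_logprob_grad(matrix(pl, 1), l))
      for (a in 1:2) {
        w <- pl[l] * pa[a]
        adv <- rew[l, a] - baseline
        glp_a <- as.numeric(softmax_logprob_grad(matrix(pa, 1), a))
        g <- numeric(6)
        g[1:2] <- glp_l
        g[2 + (l - 1) * 2 + 1:2] <- glp_a
        est <- est + w * adv * g
      }
    }
    fd <- vapply(1:6, function(i) {
      tp <- theta; tm <- theta
      tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      (expected_return(tp) - expected_return(tm)) / (2 * h)
    }, numeric(1))
    rel <- max(abs(est - fd)) / max(max(abs(fd)), 1e-8)
    worst <- max(worst, rel)
  }
  worst
}

#' Synthetic burst-classification tasks for the agent
#'
#' Two seeded toy problems over one-dimensional sequences:
#' `order_task = FALSE` - class 1 carries a large localized amplitude
#' burst on a noise floor, class 2 is noise only (a linearly separable
#' attention task); `order_task = TRUE` - both classes carry one smooth
#' and one oscillatory burst of equal energy, in opposite temporal order,
#' so solving the task requires integrating more than one glimpse.
#'
#' @param n_per_class sequences per class.
#' @param len sequence length in samples.
#' @param order_task build the order-memory variant.
#' @param seed integer seed.
#' @return An `agent_dataset` with 2 classes.
#' @export
synthetic_burst_dataset <- function(n_per_class, len = 128L,
                                    order_task = FALSE, seed = 1L) {
  gauss_burst <- function(n, centre, width, amp) {
    t <- seq_len(n)
    amp * exp(-0.5 * ((t - centre) / width)^2)
  }
  osc_burst <- function(n, centre, width, amp) {
    t <- seq_len(n)
    gauss_burst(n, centre, width, amp) * sin(2 * pi * (t - centre) / 6) *
      sqrt(2)
  }
  withr::with_seed(seed, {
    xs <- vector("list", 2L * n_per_class)
    labels <- integer(2L * n_per_class)
    for (i in seq_len(2L * n_per_class)) {
      cl <- if (i <= n_per_class) 1L else 2L
      x <- stats::rnorm(len, 0, 0.3)
      if (!order_task) {
        if (cl == 1L) {
          centre <- stats::runif(1, 0.3, 0.7) * len
          x <- x + gauss_burst(len, centre, len / 30, 3)
        }
      } else {
        c1 <- stats::runif(1, 0.15, 0.40) * len
        c2 <- stats::runif(1, 0.60, 0.85) * len
        if (cl == 1L) {
          x <- x + gauss_burst(len, c1, len / 40, 2.5) +
            osc_burst(len, c2, len / 40, 2.5)
        } else {
          x <- x + osc_burst(len, c1, len / 40, 2.5) +
            gauss_burst(len, c2, len / 40, 2.5)
        }
      }
      xs[[i]] <- x
      labels[i] <- cl
    }
    agent_dataset(xs, labels,
                  class_names = if (order_task)
                    c("smooth_first", "osc_first")
                  else c("burst", "no_burst"))
  })
}
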