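#' Training configuration
#'
#' Defaults give the reference training protocol: AdamW at an initial learning rate
#' of 1e-4, batch size 16, learning rate decayed by 1% every 10 epochs,
#' 60/20/20 train/validation/test split, five-seed ensembling. Epoch count
#' and early stopping are unstated in the protocol; training runs up to
#' `max_epochs` and keeps the checkpoint with the best validation loss,
#' stopping after `early_stop_patience` epochs without improvement.
#'
#' @param learning_rate initial AdamW learning rate.
#' @param batch_size graphs per gradient step.
#' @param lr_decay_factor multiplicative decay, applied every
#'   `lr_decay_every` epochs.
#' @param lr_decay_every epochs between decays.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param weight_decay decoupled AdamW weight decay (biases excluded).
#' @param split_ratios train/validation/test proportions.
#' @param n_ensemble_seeds independent runs averaged by the ensemble.
#' @return a validated list of class `train_config`.
#' @export
trainConfig <- function(learning_rate = 1e-4, batch_size = 16L,
                        lr_decay_factor = 0.99, lr_decay_every = 10L,
                        max_epochs = 300L, early_stop_patience = 30L,
                        weight_decay = 0.01,
                        split_ratios = c(0.6, 0.2, 0.2),
                        n_ensemble_seeds = 5L) {
    cfg <- list(learning_rate = learning_rate,
                batch_size = as.integer(batch_size),
                lr_decay_factor = lr_decay_factor,
                lr_decay_every = as.integer(lr_decay_every),
                max_epochs = as.integer(max_epochs),
                early_stop_patience = as.integer(early_stop_patience),
                weight_decay = weight_decay,
                split_ratios = split_ratios,
                n_ensemble_seeds = as.integer(n_ensemble_seeds))
    if (cfg$learning_rate <= 0 || cfg$batch_size < 1L || cfg$max_epochs < 1L ||
        cfg$early_stop_patience < 1L || cfg$n_ensemble_seeds < 1L)
        stop("counts and rates must be positive")
    if (length(cfg$split_ratios) != 3L || any(cfg$split_ratios <= 0) ||
        abs(sum(cfg$split_ratios) - 1) > 1e-6)
        stop("split_ratios must be three positive proportions summing to 1")
    class(cfg) <- "train_config"
    cfg
}

#' Class-stratified train/validation/test split
#'
#' Sizes are the rounded ratios of the total (99 samples at 60/20/20 give
#' 59/20/20); stratification keeps the class proportions in every split.
#' Splits are disjoint, exhaustive and seeded.
#'
#' @param x a [MicrobiomeExperiment-class] with labels, or a named 0/1
#'   label vector.
#' @param ratios train/validation/test proportions.
#' @param seed integer seed.
#' @return list with character vectors `train`, `validation`, `test`.
#' @export
splitDataset <- function(x, ratios = c(0.6, 0.2, 0.2), seed) {
    if (missing(seed)) stop("seed is mandatory")
    labels <- if (is(x, "MicrobiomeExperiment")) sampleLabels(x) else x
    if (is.null(labels)) stop("labels are required to split")
    n <- length(labels)
    if (n < 5L) stop("need at least 5 samples to split")
    nval <- round(ratios[2L] * n)
    ntest <- round(ratios[3L] * n)
    withr::with_seed(as.integer(seed), {
        ids <- names(labels)
        val <- character(); test <- character()
        for (cl in c(0L, 1L)) {
            cls <- sample(ids[labels == cl])
            nv <- round(length(cls) * ratios[2L])
            nt <- round(length(cls) * ratios[3L])
            val <- c(val, cls[seq_len(nv)])
            test <- c(test, cls[nv + seq_len(nt)])
        }
        # per-class rounding may drift from the global rounded sizes; adjust
        # from the training pool while preserving stratification order
        train <- setdiff(ids, c(val, test))
        adjust <- function(set, size) {
            while (length(set) < size && length(train) > 0L) {
                mv <- train[length(train)]; train <<- train[-length(train)]
                set <- c(set, mv)
            }
            set
        }
        val <- adjust(val, nval); test <- adjust(test, ntest)
        splits <- list(train = ids[ids %in% train],
                       validation = ids[ids %in% val],
                       test = ids[ids %in% test])
        for (nm in names(splits)) {
            sl <- labels[splits[[nm]]]
            if (!any(sl == 0L) || !any(sl == 1L))
                stop("split '", nm, "' has no members of one class; ",
                     "use a different seed or ratios")
        }
        splits
    })
}

.adamwInit <- function(params) {
    zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
    list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

.adamwStep <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    step1 <- function(p, g, m, v, decay) {
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g * g
        p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + decay * p)
        list(p = p, m = m, v = v)
    }
    for (nm in names(params)) {
        decay <- if (nm == "mlpb") 0 else weight_decay
        if (is.list(params[[nm]])) {
            for (j in seq_along(params[[nm]])) {
                r <- step1(params[[nm]][[j]], grads[[nm]][[j]],
                           state$m[[nm]][[j]], state$v[[nm]][[j]], decay)
                params[[nm]][[j]] <- r$p
                state$m[[nm]][[j]] <- r$m
                state$v[[nm]][[j]] <- r$v
            }
        } else {
            r <- step1(params[[nm]], grads[[nm]], state$m[[nm]],
                       state$v[[nm]], decay)
            params[[nm]] <- r$p
            state$m[[nm]] <- r$m
            state$v[[nm]] <- r$v
        }
    }
    list(params = params, state = state)
}

.evalLoss <- function(params, config, payloads, labels) {
    .gatBatchCpp(params, config, payloads, labels, FALSE, FALSE)$loss
}

#' Train the graph attention classifier
#'
#' Minimizes binary cross-entropy with AdamW over mini-batches of sample
#' graphs, decaying the learning rate on the configured schedule, and
#' returns the parameters with the lowest validation loss. Fully
#' reproducible given the seed (initialization, batch order and dropout all
#' draw from one seeded stream).
#'
#' @param graphs named list of [SampleGraph-class] objects covering the
#'   train and validation ids.
#' @param labels named 0/1 vector.
#' @param split list with `train` and `validation` id vectors (see
#'   [splitDataset()]).
#' @param modelConfig a [modelConfig()].
#' @param trainConfig a [trainConfig()].
#' @param seed integer seed.
#' @param verbose print per-epoch progress.
#' @return list with `model` (a [GATModel-class]) and `log` (a data.frame
#'   of epoch, train_loss, val_loss, lr).
#' @export
trainModel <- function(graphs, labels, split, modelConfig, trainConfig,
                       seed, verbose = FALSE) {
    stopifnot(inherits(modelConfig, "model_config"),
              inherits(trainConfig, "train_config"))
    if (missing(seed)) stop("seed is mandatory")
    tr <- split$train; va <- split$validation
    if (!length(tr) || !length(va)) stop("degenerate train/validation split")
    gd <- modelConfig$genomic_dim
    ptr <- lapply(graphs[tr], .graphPayload, genomicDim = gd)
    pva <- lapply(graphs[va], .graphPayload, genomicDim = gd)
    ytr <- as.numeric(labels[tr]); yva <- as.numeric(labels[va])

    model <- initModel(modelConfig, seed = seed)
    params <- model@params
    cfg <- model@config
    withr::with_seed(as.integer(seed) + 1L, {
        opt <- .adamwInit(params)
        best <- list(loss = Inf, params = params, epoch = 0L)
        log <- vector("list", trainConfig$max_epochs)
        wait <- 0L
        for (epoch in seq_len(trainConfig$max_epochs)) {
            lr <- trainConfig$learning_rate *
                trainConfig$lr_decay_factor^((epoch - 1L) %/% trainConfig$lr_decay_every)
            ord <- sample(length(ptr))
            bstarts <- seq(1L, length(ord), by = trainConfig$batch_size)
            tl <- 0
            for (b in bstarts) {
                idx <- ord[b:min(b + trainConfig$batch_size - 1L, length(ord))]
                res <- .gatBatchCpp(params, cfg, ptr[idx], ytr[idx],
                                    TRUE, TRUE)
                if (!is.finite(res$loss))
                    stop("training diverged (non-finite loss) at epoch ",
                         epoch, "; reduce the learning rate")
                tl <- tl + res$loss * length(idx)
                upd <- .adamwStep(params, res$grads, opt, lr,
                                  trainConfig$weight_decay)
                params <- upd$params; opt <- upd$state
            }
            tl <- tl / length(ptr)
            vl <- .evalLoss(params, cfg, pva, yva)
            log[[epoch]] <- data.frame(epoch = epoch, train_loss = tl,
                                       val_loss = vl, lr = lr)
            if (verbose && epoch %% 10L == 0L)
                message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, tl, vl))
            if (vl < best$loss - 1e-9) {
                best <- list(loss = vl, params = params, epoch = epoch)
                wait <- 0L
            } else {
                wait <- wait + 1L
                if (wait >= trainConfig$early_stop_patience) break
            }
        }
        model@params <- best$params
        list(model = model, log = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
             best_epoch = best$epoch, best_val_loss = best$loss)
    })
}

#' Train an ensemble of independently seeded models
#'
#' @inheritParams trainModel
#' @param seeds integer vector of run seeds (default
#'   `seed + 0:(n_ensemble_seeds-1)`).
#' @param seed base seed used when `seeds` is NULL.
#' @return list of trained [GATModel-class] objects (one per seed), with the
#'   per-run training logs in `attr(, "logs")`.
#' @export
trainEnsemble <- function(graphs, labels, split, modelConfig, trainConfig,
                          seed, seeds = NULL, verbose = FALSE) {
    if (is.null(seeds))
        seeds <- as.integer(seed) + seq_len(trainConfig$n_ensemble_seeds) - 1L
    runs <- lapply(seeds, function(s)
        trainModel(graphs, labels, split, modelConfig, trainConfig,
                   seed = s, verbose = verbose))
    models <- lapply(runs, `[[`, "model")
    attr(models, "logs") <- lapply(runs, `[[`, "log")
    attr(models, "seeds") <- seeds
    models
}
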