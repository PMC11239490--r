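# Losses, augmentation, training loop, calibration and the predictor interface.

#' Training configuration
#'
#' Defaults: AdamW at learning rate 1e-4 with weight decay 2e-5, a schedule
#' reducing the rate to a fifth after 4 epochs without validation improvement,
#' batch size 256, at most 200 epochs with early stopping after 12 epochs
#' without improvement, PolyLoss with epsilon 1 and label smoothing 0.1.
#'
#' @param lr Learning rate.
#' @param lr_factor,lr_patience Schedule: multiply \code{lr} by
#'   \code{lr_factor} after \code{lr_patience} epochs without improvement.
#' @param weight_decay Decoupled weight decay.
#' @param batch Batch size.
#' @param epochs Maximum epochs.
#' @param early_stop Stop after this many epochs without improvement.
#' @param label_smoothing,poly_epsilon PolyLoss parameters.
#' @param seed RNG seed for shuffling, dropout and augmentation.
#' @return List of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(lr = 1e-4, lr_factor = 0.2, lr_patience = 4L,
                        weight_decay = 2e-5, batch = 256L, epochs = 200L,
                        early_stop = 12L, label_smoothing = 0.1,
                        poly_epsilon = 1, seed = 1L) {
  stopifnot(lr > 0, lr_patience < early_stop, batch >= 1L)
  structure(list(lr = lr, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 weight_decay = weight_decay, batch = as.integer(batch),
                 epochs = as.integer(epochs),
                 early_stop = as.integer(early_stop),
                 label_smoothing = label_smoothing,
                 poly_epsilon = poly_epsilon, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Augmentation configuration
#'
#' Training-time and test-time augmentation: random low-intensity peak removal,
#' peak intensity jitter, new peak addition, precursor adduct formation
#' (acetate/sodium) and random noise on the precursor m/z (within ±0.5 Da) and
#' retention time (within ±10 percent).
#'
#' @param peak_drop_frac Probability of removing each low-intensity peak.
#' @param intensity_jitter_sd SD of the multiplicative log-normal intensity
#'   jitter.
#' @param new_peak_rate Expected number of spurious peaks added.
#' @param adduct_prob Probability of shifting the precursor by a random adduct.
#' @param adducts Adducts to draw from.
#' @param precursor_jitter Uniform precursor m/z noise half-width (Da).
#' @param rt_jitter Relative retention-time noise half-width.
#' @return List of class \code{"AugmentConfig"}.
#' @export
augmentConfig <- function(peak_drop_frac = 0.2, intensity_jitter_sd = 0.1,
                          new_peak_rate = 2, adduct_prob = 0.1,
                          adducts = c("acetate", "sodium"),
                          precursor_jitter = 0.5, rt_jitter = 0.1) {
  stopifnot(peak_drop_frac >= 0, peak_drop_frac <= 1, adduct_prob >= 0,
            adduct_prob <= 1)
  structure(list(peak_drop_frac = peak_drop_frac,
                 intensity_jitter_sd = intensity_jitter_sd,
                 new_peak_rate = new_peak_rate, adduct_prob = adduct_prob,
                 adducts = adducts, precursor_jitter = precursor_jitter,
                 rt_jitter = rt_jitter),
            class = "AugmentConfig")
}

#' Augment a spectrum
#'
#' Applies the configured augmentations to a raw \linkS4class{Spectrum}:
#' low-intensity peaks (bottom intensity quartile) are dropped independently,
#' intensities receive multiplicative log-normal jitter, spurious peaks are
#' added uniformly over the observed m/z range, and the precursor m/z and
#' retention time are perturbed (adduct shift with probability
#' \code{adduct_prob}, then uniform noise). Reproducible under \code{seed}.
#'
#' @param s A \linkS4class{Spectrum}.
#' @param acfg An \code{\link{augmentConfig}}.
#' @param seed Integer seed (\code{NULL} uses the current RNG stream).
#' @return The augmented \linkS4class{Spectrum}.
#' @export
augmentSpectrum <- function(s, acfg = augmentConfig(), seed = NULL) {
  .withSeed(seed, {
    mz <- s@mz; int <- s@intensity
    if (length(mz) > 0L && acfg$peak_drop_frac > 0) {
      low <- int <= stats::quantile(int, 0.25)
      drop <- low & stats::runif(length(int)) < acfg$peak_drop_frac
      if (all(drop)) drop[which.max(int)] <- FALSE
      mz <- mz[!drop]; int <- int[!drop]
    }
    if (acfg$intensity_jitter_sd > 0 && length(int) > 0L) {
      int <- int * exp(stats::rnorm(length(int), 0, acfg$intensity_jitter_sd))
    }
    nNew <- stats::rpois(1L, acfg$new_peak_rate)
    if (nNew > 0L && length(mz) > 0L) {
      mz <- c(mz, stats::runif(nNew, min(mz), max(mz)))
      int <- c(int, stats::runif(nNew, 0, stats::quantile(int, 0.25)))
    }
    prec <- s@precursorMz
    if (stats::runif(1L) < acfg$adduct_prob) {
      prec <- prec + .ADDUCT_SHIFTS[[sample(acfg$adducts, 1L)]]
    }
    prec <- prec + stats::runif(1L, -acfg$precursor_jitter,
                                acfg$precursor_jitter)
    rt <- s@rt
    if (!is.na(rt)) rt <- rt * (1 + stats::runif(1L, -acfg$rt_jitter,
                                                 acfg$rt_jitter))
    spectrum(mz, int, prec, rt = rt, meta = s@meta)
  })
}

# Augmentation on the binned representation (used in the training loop and
# test-time augmentation, where inputs are already binned).
.augmentBinned <- function(b, acfg) {
  int <- b@intensities
  rem <- b@remainders
  nz <- which(int > 0)
  if (length(nz) > 1L && acfg$peak_drop_frac > 0) {
    low <- nz[int[nz] <= stats::quantile(int[nz], 0.25)]
    drop <- low[stats::runif(length(low)) < acfg$peak_drop_frac]
    if (length(drop) >= length(nz)) drop <- drop[-1L]
    int[drop] <- 0; rem[drop] <- 0
  }
  nz <- which(int > 0)
  if (acfg$intensity_jitter_sd > 0 && length(nz) > 0L) {
    int[nz] <- int[nz] * exp(stats::rnorm(length(nz), 0,
                                          acfg$intensity_jitter_sd))
  }
  nNew <- stats::rpois(1L, acfg$new_peak_rate)
  if (nNew > 0L && length(nz) > 0L) {
    bins <- sample(length(int), nNew)
    int[bins] <- int[bins] + stats::runif(nNew, 0, stats::quantile(int[nz], 0.25))
    rem[bins] <- stats::runif(nNew, 0, binWidth() * 0.999)
  }
  tot <- sum(int)
  if (tot > 0) int <- int / tot
  prec <- b@precursorMz
  if (stats::runif(1L) < acfg$adduct_prob) {
    prec <- prec + .ADDUCT_SHIFTS[[sample(acfg$adducts, 1L)]]
  }
  prec <- prec + stats::runif(1L, -acfg$precursor_jitter, acfg$precursor_jitter)
  rtn <- min(max(b@rtNorm * (1 + stats::runif(1L, -acfg$rt_jitter,
                                              acfg$rt_jitter)), 0), 1)
  new("BinnedSpectrum", intensities = int, remainders = rem, rtNorm = rtn,
      precursorMz = prec, meta = b@meta)
}

#' Expected-distance loss of a predicted class distribution
#'
#' The expectation of a per-class distance vector under the predicted
#' (post-softmax) distribution, averaged over the batch: confidently predicting
#' a class structurally far from the target is penalized in proportion to that
#' distance.
#'
#' @param probs Numeric vector (one sample) or K x N matrix of class
#'   probabilities.
#' @param distances Numeric vector of per-class distances to the target (or
#'   K x N matrix, one column per sample), each in [0, 1].
#' @return Scalar loss in [0, 1] when distances are.
#' @examples
#' distanceLoss(c(1, 0, 0), c(0, 0.4, 0.9))        # 0: all mass on the target
#' distanceLoss(c(0.25, 0.25, 0.25, 0.25), rep(0.3, 4))  # 0.3: constant
#' @export
distanceLoss <- function(probs, distances) {
  probs <- as.matrix(probs)
  distances <- if (is.matrix(distances)) distances else
    matrix(distances, nrow = length(distances), ncol = ncol(probs))
  if (nrow(probs) != nrow(distances)) {
    stop("probs and distances must have the same number of classes",
         call. = FALSE)
  }
  mean(colSums(probs * distances))
}

#' PolyLoss with label smoothing
#'
#' Cross-entropy plus \code{epsilon} times the complement of the (smoothed)
#' target probability mass, averaged over the batch.
#'
#' @param logits K x N matrix of class scores (or vector for one sample).
#' @param targets Integer class indices (1-based), length N.
#' @param epsilon PolyLoss epsilon (default 1).
#' @param smoothing Label smoothing mass spread over all classes (default 0.1).
#' @return Scalar loss.
#' @export
polyLoss <- function(logits, targets, epsilon = 1, smoothing = 0.1) {
  logits <- as.matrix(logits)
  p <- .softmax(logits)
  K <- nrow(p); N <- ncol(p)
  q <- matrix(smoothing / K, K, N)
  q[cbind(targets, seq_len(N))] <- q[cbind(targets, seq_len(N))] +
    (1 - smoothing)
  ce <- -colSums(q * log(pmax(p, 1e-12)))
  poly <- epsilon * (1 - colSums(q * p))
  mean(ce + poly)
}

.softmax <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# Total loss and gradient wrt logits: PolyLoss (label-smoothed) plus the
# structure- and composition-distance expectations.
.lossGrad <- function(logits, targets, tcfg, D_struct = NULL, D_comp = NULL) {
  K <- nrow(logits); N <- ncol(logits)
  p <- .softmax(logits)
  q <- matrix(tcfg$label_smoothing / K, K, N)
  ti <- cbind(targets, seq_len(N))
  q[ti] <- q[ti] + (1 - tcfg$label_smoothing)
  eps <- tcfg$poly_epsilon
  ce <- -colSums(q * log(pmax(p, 1e-12)))
  qp <- colSums(q * p)
  loss <- mean(ce + eps * (1 - qp))
  dz <- (p - q) + eps * (p * rep(qp, each = K) - q * p)
  for (D in list(D_struct, D_comp)) {
    if (is.null(D)) next
    d <- D[, targets, drop = FALSE]
    pd <- colSums(p * d)
    loss <- loss + mean(pd)
    dz <- dz + p * (d - rep(pd, each = K))
  }
  list(loss = loss, dlogits = dz / N)
}

#' Pairwise distance matrices over a glycan library
#'
#' Structure distances are cosine distances between motif fingerprints on the
#' library-wide vocabulary; composition distances are cosine distances between
#' base compositions.
#'
#' @param library List of \linkS4class{GlycanGraph} objects.
#' @return List with matrices \code{structure} and \code{composition}
#'   (K x K, zero diagonal, symmetric).
#' @export
distanceMatrices <- function(library) {
  K <- length(library)
  vocab <- motifVocabulary(library)
  fps <- vapply(library, fingerprint, integer(length(vocab)), vocab = vocab)
  comps <- vapply(library, toComposition, integer(length(.COMP_CLASSES)))
  cosDistMat <- function(M) {
    nrm <- sqrt(colSums(M^2))
    S <- crossprod(M) / outer(nrm, nrm)
    S[!is.finite(S)] <- 0
    D <- 1 - S
    D[D < 0] <- 0; D[D > 1] <- 1
    diag(D) <- 0
    D
  }
  list(structure = cosDistMat(fps), composition = cosDistMat(comps))
}

#' Train the classifier
#'
#' AdamW with the configured schedule and early stopping; the loss is PolyLoss
#' (label smoothing 0.1, epsilon 1) plus, when distance matrices are given, the
#' structure- and composition-distance expectations. Augmentation (when
#' \code{acfg} is non-NULL) is applied to every training batch on the binned
#' representation. The best-validation-loss parameters are restored at the end.
#'
#' @param model From \code{\link{buildModel}}.
#' @param binned_train,y_train Training set: list of
#'   \linkS4class{BinnedSpectrum} and 1-based class labels.
#' @param binned_val,y_val Validation set used for the schedule, early stopping
#'   and model selection.
#' @param tcfg A \code{\link{trainConfig}}.
#' @param acfg An \code{\link{augmentConfig}} or NULL for no augmentation.
#' @param D_struct,D_comp Optional K x K distance matrices (see
#'   \code{\link{distanceMatrices}}).
#' @param verbose Print per-epoch progress.
#' @return The model with trained parameters and a \code{history} data.frame
#'   (epoch, train_loss, val_loss, val_acc, lr).
#' @export
trainModel <- function(model, binned_train, y_train, binned_val, y_val,
                       tcfg = trainConfig(), acfg = augmentConfig(),
                       D_struct = NULL, D_comp = NULL, verbose = FALSE) {
  stopifnot(length(binned_train) == length(y_train), length(y_train) > 0L,
            length(unique(y_train)) >= 2L)
  .withSeed(tcfg$seed, {
    valInputs <- .buildInputs(binned_val)
    state <- list(t = 0L, m = list(), v = list())
    lr <- tcfg$lr
    best <- list(loss = Inf, params = model$params, epoch = 0L)
    sinceBest <- 0L
    sinceLR <- 0L
    hist <- list()
    nTr <- length(binned_train)
    for (epoch in seq_len(tcfg$epochs)) {
      perm <- sample(nTr)
      starts <- seq(1L, nTr, by = tcfg$batch)
      trLoss <- 0
      for (st in starts) {
        idx <- perm[seq.int(st, min(st + tcfg$batch - 1L, nTr))]
        bb <- binned_train[idx]
        if (!is.null(acfg)) bb <- lapply(bb, .augmentBinned, acfg = acfg)
        inputs <- .buildInputs(bb)
        fw <- .nnForward(model, inputs, train = TRUE)
        lg <- .lossGrad(fw$logits, y_train[idx], tcfg, D_struct, D_comp)
        trLoss <- trLoss + lg$loss * length(idx)
        grads <- .nnBackward(model, fw$cache, lg$dlogits)
        upd <- .adamStep(model$params, grads, state, lr, tcfg$weight_decay)
        model$params <- upd$params
        state <- upd$state
        fw <- NULL; grads <- NULL; inputs <- NULL
      }
      gc(verbose = FALSE)
      trLoss <- trLoss / nTr
      fwv <- .nnForward(model, valInputs, train = FALSE, keep_cache = FALSE)
      lgv <- .lossGrad(fwv$logits, y_val, tcfg, D_struct, D_comp)
      valAcc <- mean(apply(fwv$logits, 2L, which.max) == y_val)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = trLoss,
                                  val_loss = lgv$loss, val_acc = valAcc,
                                  lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f  lr %.2g",
                        epoch, trLoss, lgv$loss, valAcc, lr))
      }
      if (lgv$loss < best$loss - 1e-6) {
        best <- list(loss = lgv$loss, params = model$params, epoch = epoch)
        sinceBest <- 0L; sinceLR <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        sinceLR <- sinceLR + 1L
        if (sinceLR >= tcfg$lr_patience) {
          lr <- lr * tcfg$lr_factor
          sinceLR <- 0L
        }
        if (sinceBest >= tcfg$early_stop) break
      }
    }
    model$params <- best$params
    model$history <- do.call(rbind, hist)
    model
  })
}

#' Calibrated top-k prediction with test-time augmentation
#'
#' Logits are divided by \code{platt_factor} (single-parameter Platt scaling)
#' before the softmax; the probabilities of \code{tta_rounds} independent
#' inferences under the training augmentation are averaged. With
#' \code{tta_rounds = 1} no augmentation is applied and the result is the plain
#' calibrated softmax.
#'
#' @param model A trained model.
#' @param binned A \linkS4class{BinnedSpectrum}.
#' @param platt_factor Calibration divisor (default 1.15).
#' @param tta_rounds Augmented inference rounds to average (default 5).
#' @param k Candidates to return (clipped to the class count with a warning).
#' @param acfg Augmentation used for TTA.
#' @param seed Seed for the augmentation rounds.
#' @return data.frame with columns \code{class} (index) and \code{score},
#'   sorted descending; scores over all classes sum to 1.
#' @export
calibrateAndPredict <- function(model, binned, platt_factor = 1.15,
                                tta_rounds = 5L, k = 25L,
                                acfg = augmentConfig(), seed = NULL) {
  K <- model$cfg$n_classes
  if (k > K) {
    warning("k exceeds the number of classes; clipping")
    k <- K
  }
  probs <- .withSeed(seed, {
    acc <- numeric(K)
    for (round_ in seq_len(tta_rounds)) {
      b <- if (tta_rounds > 1L && !is.null(acfg)) .augmentBinned(binned, acfg)
           else binned
      fw <- .nnForward(model, .buildInputs(list(b)), train = FALSE,
                       keep_cache = FALSE)
      acc <- acc + .softmax(fw$logits / platt_factor)[, 1L]
    }
    acc / tta_rounds
  })
  o <- order(-probs)[seq_len(k)]
  data.frame(class = o, score = probs[o])
}

#' Wrap a trained model into the predictor interface
#'
#' The returned object exposes \code{labels} (canonical structures) and
#' \code{scores(binned)}, the calibrated TTA-averaged probability vector, as
#' consumed by \code{\link{wrapInference}}.
#'
#' @param model A trained model whose classes index \code{library}.
#' @param library List of \linkS4class{GlycanGraph} (the class space).
#' @param platt_factor,tta_rounds,acfg See \code{\link{calibrateAndPredict}}.
#' @return Predictor list.
#' @export
nnPredictor <- function(model, library, platt_factor = 1.15, tta_rounds = 5L,
                        acfg = augmentConfig()) {
  stopifnot(model$cfg$n_classes == length(library))
  labels <- vapply(library, serializeIUPAC, character(1))
  list(
    labels = labels,
    library = library,
    scores = function(binned) {
      res <- calibrateAndPredict(model, binned, platt_factor = platt_factor,
                                 tta_rounds = tta_rounds,
                                 k = model$cfg$n_classes, acfg = acfg)
      out <- numeric(length(labels))
      out[res$class] <- res$score
      out
    }
  )
}
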