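#' @include nets-core.R
NULL

# ---- architecture plan -------------------------------------------------------
# A plan is a list of nodes executed in order. Node fields:
#   op   : conv | bn | relu | pool | upsample | concat
#   name : parameter prefix (conv, bn)
#   from : index of the input node (0 = network input)
#   with : tag name of the second input (concat)
#   tag  : optional tag for later reference (skip connections)
#   cin, cout : conv channel counts
# Head activations are applied outside the plan so that fused
# loss/activation gradients can be used during training.

planStacked <- function(spec) {
  nodes <- list()
  add <- function(...) nodes[[length(nodes) + 1L]] <<- list(...)
  cur <- function() length(nodes)
  cin <- spec$inputFrames
  ws <- spec$encoderWidths
  cps <- spec$convsPerStage
  for (s in seq_along(ws)) {
    for (j in seq_len(cps)) {
      add(op = "conv", name = sprintf("enc%d_%d", s, j), from = cur(),
          cin = cin, cout = ws[s])
      add(op = "bn", name = sprintf("encbn%d_%d", s, j), from = cur(),
          cout = ws[s])
      add(op = "relu", from = cur(),
          tag = if (j == cps) sprintf("skip%d", s) else NULL)
      cin <- ws[s]
    }
    add(op = "pool", from = cur())
  }
  for (j in seq_len(cps)) {
    add(op = "conv", name = sprintf("lat_%d", j), from = cur(), cin = cin,
        cout = spec$latentWidth)
    add(op = "bn", name = sprintf("latbn_%d", j), from = cur(),
        cout = spec$latentWidth)
    add(op = "relu", from = cur())
    cin <- spec$latentWidth
  }
  planDecoder(nodes, cin, spec)
}

planDecoder <- function(nodes, cin, spec) {
  add <- function(...) nodes[[length(nodes) + 1L]] <<- list(...)
  cur <- function() length(nodes)
  ws <- spec$encoderWidths
  cps <- spec$convsPerStage
  for (s in rev(seq_along(ws))) {
    add(op = "upsample", from = cur())
    if (isTRUE(spec$skips)) {
      add(op = "concat", from = cur(), with = sprintf("skip%d", s),
          cin2 = ws[s])
      cin <- cin + ws[s]
    }
    for (j in seq_len(cps)) {
      add(op = "conv", name = sprintf("dec%d_%d", s, j), from = cur(),
          cin = cin, cout = ws[s])
      add(op = "bn", name = sprintf("decbn%d_%d", s, j), from = cur(),
          cout = ws[s])
      add(op = "relu", from = cur())
      cin <- ws[s]
    }
  }
  add(op = "conv", name = "head", from = cur(), cin = cin,
      cout = spec$outChannels)
  nodes
}

planEncoderM2 <- function(spec) {
  sp <- spec
  sp$inputFrames <- 1L
  nodes <- planStacked(sp)
  # keep nodes up to (and including) the last encoder pool
  lastPool <- max(which(vapply(nodes, function(n) n$op == "pool", TRUE)))
  nodes[seq_len(lastPool)]
}

planDecoderM2 <- function(spec) {
  planDecoder(list(), spec$latentWidth, spec)
}

heInit <- function(k, cin, cout) {
  matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

initPlanParams <- function(plan, params, k = 3L) {
  for (n in plan) {
    if (n$op == "conv") {
      params[[paste0(n$name, ".W")]] <- heInit(k, n$cin, n$cout)
      params[[paste0(n$name, ".b")]] <- numeric(n$cout)
    } else if (n$op == "bn") {
      params[[paste0(n$name, ".g")]] <- rep(1, n$cout)
      params[[paste0(n$name, ".be")]] <- numeric(n$cout)
    }
  }
  params
}

#' Build a network model
#'
#' Constructs one of the five encoder-decoder variants with freshly
#' initialized parameters (He initialization, seeded). The encoder applies
#' \code{convsPerStage} convolution (3x3) + batch-norm + ReLU blocks per
#' stage followed by 2x2 max pooling; the decoder mirrors it with 2x nearest
#' upsampling. M3 adds long skip connections (channel concatenation) at every
#' resolution; M2 encodes each input frame with shared weights and aggregates
#' the sequence with a convolutional LSTM in the latent space, whose final
#' hidden state feeds the decoder. Heads: tanh 2-channel trigonometric phase
#' (M1/M2/M3), softmax 2-channel class map (M1A), sigmoid 1-channel PS
#' probability (M1B).
#'
#' @param variant "M1", "M2", "M3", "M1A" or "M1B".
#' @param inputFrames number of input frames N_t.
#' @param side square input size, divisible by 8.
#' @param encoderWidths integer(3) channel widths of the encoder stages.
#' @param latentWidth latent channel width.
#' @param convsPerStage conv blocks per stage (default 3).
#' @param seed initialization seed.
#' @return a \linkS4class{RotorNet}.
#' @export
buildModel <- function(variant, inputFrames = 5L, side = 128L,
                       encoderWidths = c(64L, 128L, 256L), latentWidth = 512L,
                       convsPerStage = 3L, seed = 1L) {
  if (side %% 8L != 0L) stop("side must be divisible by 8")
  head <- switch(variant, M1 = , M2 = , M3 = "tanh2", M1A = "softmax2",
                 M1B = "sigmoid1", stop("unknown variant: ", variant))
  spec <- list(inputFrames = as.integer(inputFrames), side = as.integer(side),
               encoderWidths = as.integer(encoderWidths),
               latentWidth = as.integer(latentWidth),
               convsPerStage = as.integer(convsPerStage),
               skips = variant == "M3", head = head,
               outChannels = if (head == "sigmoid1") 1L else 2L)
  params <- list()
  withSeed(seed, {
    if (variant == "M2") {
      params <- initPlanParams(planEncoderM2(spec), params)
      cx <- spec$encoderWidths[length(spec$encoderWidths)]
      ch <- spec$latentWidth
      params[["lstm.Wx"]] <- heInit(3L, cx, 4L * ch)
      params[["lstm.Wh"]] <- heInit(3L, ch, 4L * ch) * 0.5
      b <- numeric(4L * ch)
      b[(ch + 1):(2 * ch)] <- 1  # forget-gate bias
      params[["lstm.b"]] <- b
      params <- initPlanParams(planDecoderM2(spec), params)
    } else {
      params <- initPlanParams(planStacked(spec), params)
    }
  })
  new("RotorNet", variant = variant, spec = spec, params = params,
      state = list(history = data.frame()))
}

# ---- tape execution ---------------------------------------------------------

forwardTape <- function(plan, params, state, X, train) {
  outs <- vector("list", length(plan))
  caches <- vector("list", length(plan))
  tagIdx <- list()
  getOut <- function(i) if (i == 0L) X else outs[[i]]
  for (i in seq_along(plan)) {
    n <- plan[[i]]
    x <- getOut(n$from)
    if (n$op == "conv") {
      outs[[i]] <- conv2d_forward(x, params[[paste0(n$name, ".W")]],
                                  params[[paste0(n$name, ".b")]], 3L)
      caches[[i]] <- list(x = x)
    } else if (n$op == "bn") {
      r <- bnForward(x, params[[paste0(n$name, ".g")]],
                     params[[paste0(n$name, ".be")]], state, n$name, train)
      outs[[i]] <- r$y
      caches[[i]] <- r$cache
      state <- r$state
    } else if (n$op == "relu") {
      m <- x > 0
      outs[[i]] <- x * m
      caches[[i]] <- list(m = m)
    } else if (n$op == "pool") {
      r <- maxpool2_forward(x)
      outs[[i]] <- r$y
      caches[[i]] <- list(which = r$which, H = dims4(x)[1], W = dims4(x)[2])
    } else if (n$op == "upsample") {
      outs[[i]] <- upsample2_forward(x)
    } else if (n$op == "concat") {
      y <- getOut(tagIdx[[n$with]])
      dx <- dims4(x); dy <- dims4(y)
      out <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
      out[, , seq_len(dx[3]), ] <- x
      out[, , dx[3] + seq_len(dy[3]), ] <- y
      outs[[i]] <- out
      caches[[i]] <- list(c1 = dx[3], c2 = dy[3], withIdx = tagIdx[[n$with]])
    }
    if (!is.null(n$tag)) tagIdx[[n$tag]] <- i
  }
  list(out = outs[[length(plan)]], outs = outs, caches = caches,
       state = state)
}

backwardTape <- function(plan, params, fwd, dOut) {
  douts <- vector("list", length(plan))
  douts[[length(plan)]] <- dOut
  grads <- list()
  addG <- function(name, g) {
    grads[[name]] <<- if (is.null(grads[[name]])) g else grads[[name]] + g
  }
  dX <- NULL
  addD <- function(i, g) {
    if (i == 0L) {
      dX <<- if (is.null(dX)) g else dX + g
    } else {
      douts[[i]] <<- if (is.null(douts[[i]])) g else douts[[i]] + g
    }
    invisible(NULL)
  }
  for (i in rev(seq_along(plan))) {
    dy <- douts[[i]]
    if (is.null(dy)) next
    n <- plan[[i]]
    if (n$op == "conv") {
      r <- conv2d_backward(fwd$caches[[i]]$x, params[[paste0(n$name, ".W")]],
                           dy, 3L)
      addG(paste0(n$name, ".W"), r$dW)
      addG(paste0(n$name, ".b"), r$db)
      addD(n$from, r$dX)
    } else if (n$op == "bn") {
      r <- bnBackward(dy, params[[paste0(n$name, ".g")]], fwd$caches[[i]])
      addG(paste0(n$name, ".g"), r$dgamma)
      addG(paste0(n$name, ".be"), r$dbeta)
      addD(n$from, r$dx)
    } else if (n$op == "relu") {
      addD(n$from, dy * fwd$caches[[i]]$m)
    } else if (n$op == "pool") {
      addD(n$from, maxpool2_backward(dy, fwd$caches[[i]]$which,
                                     fwd$caches[[i]]$H, fwd$caches[[i]]$W))
    } else if (n$op == "upsample") {
      addD(n$from, upsample2_backward(dy))
    } else if (n$op == "concat") {
      c1 <- fwd$caches[[i]]$c1; c2 <- fwd$caches[[i]]$c2
      addD(n$from, dy[, , seq_len(c1), , drop = FALSE])
      addD(fwd$caches[[i]]$withIdx, dy[, , c1 + seq_len(c2), , drop = FALSE])
    }
  }
  list(grads = grads, dX = dX)
}

# ---- ConvLSTM ---------------------------------------------------------------

convlstmForward <- function(params, xs, ch) {
  d <- dims4(xs[[1]])
  h <- array(0, c(d[1], d[2], ch, d[4]))
  cc <- h
  zb <- numeric(4L * ch)
  caches <- vector("list", length(xs))
  idx <- function(j) ((j - 1) * ch + 1):(j * ch)
  for (t in seq_along(xs)) {
    gx <- conv2d_forward(xs[[t]], params[["lstm.Wx"]], params[["lstm.b"]], 3L)
    gh <- conv2d_forward(h, params[["lstm.Wh"]], zb, 3L)
    g <- gx + gh
    i <- sigmoid(g[, , idx(1), , drop = FALSE])
    f <- sigmoid(g[, , idx(2), , drop = FALSE])
    o <- sigmoid(g[, , idx(3), , drop = FALSE])
    gg <- tanh(g[, , idx(4), , drop = FALSE])
    cprev <- cc
    hprev <- h
    cc <- f * cprev + i * gg
    tc <- tanh(cc)
    h <- o * tc
    caches[[t]] <- list(x = xs[[t]], hprev = hprev, cprev = cprev, i = i,
                        f = f, o = o, g = gg, tc = tc)
  }
  list(h = h, caches = caches)
}

convlstmBackward <- function(params, caches, dh, ch) {
  d <- dims4(dh)
  dc <- array(0, dim(dh))
  grads <- list(`lstm.Wx` = array(0, dim(params[["lstm.Wx"]])),
                `lstm.Wh` = array(0, dim(params[["lstm.Wh"]])),
                `lstm.b` = numeric(length(params[["lstm.b"]])))
  dxs <- vector("list", length(caches))
  for (t in rev(seq_along(caches))) {
    ca <- caches[[t]]
    do <- dh * ca$tc
    dcc <- dc + dh * ca$o * (1 - ca$tc^2)
    df <- dcc * ca$cprev
    di <- dcc * ca$g
    dg <- dcc * ca$i
    dc <- dcc * ca$f
    dgate <- array(0, c(d[1], d[2], 4L * ch, d[4]))
    idx <- function(j) ((j - 1) * ch + 1):(j * ch)
    dgate[, , idx(1), ] <- di * ca$i * (1 - ca$i)
    dgate[, , idx(2), ] <- df * ca$f * (1 - ca$f)
    dgate[, , idx(3), ] <- do * ca$o * (1 - ca$o)
    dgate[, , idx(4), ] <- dg * (1 - ca$g^2)
    rx <- conv2d_backward(ca$x, params[["lstm.Wx"]], dgate, 3L)
    rh <- conv2d_backward(ca$hprev, params[["lstm.Wh"]], dgate, 3L)
    grads[["lstm.Wx"]] <- grads[["lstm.Wx"]] + rx$dW
    grads[["lstm.b"]] <- grads[["lstm.b"]] + rx$db
    grads[["lstm.Wh"]] <- grads[["lstm.Wh"]] + rh$dW
    dxs[[t]] <- rx$dX
    dh <- rh$dX
  }
  list(grads = grads, dxs = dxs)
}

# ---- full network forward / backward ----------------------------------------

netForward <- function(net, X, train = FALSE) {
  X <- as4(X)
  spec <- net@spec
  state <- net@state
  if (net@variant == "M2") {
    d <- dims4(X)
    encPlan <- planEncoderM2(spec)
    encs <- vector("list", d[3])
    xs <- vector("list", d[3])
    for (t in seq_len(d[3])) {
      xt <- X[, , t, , drop = FALSE]
      encs[[t]] <- forwardTape(encPlan, net@params, state, xt, train)
      state <- encs[[t]]$state
      xs[[t]] <- encs[[t]]$out
    }
    lstm <- convlstmForward(net@params, xs, spec$latentWidth)
    decPlan <- planDecoderM2(spec)
    dec <- forwardTape(decPlan, net@params, state, lstm$h, train)
    state <- dec$state
    logits <- dec$out
    cache <- list(encPlan = encPlan, encs = encs, lstm = lstm,
                  decPlan = decPlan, dec = dec)
  } else {
    plan <- planStacked(spec)
    fwd <- forwardTape(plan, net@params, state, X, train)
    state <- fwd$state
    logits <- fwd$out
    cache <- list(plan = plan, fwd = fwd)
  }
  out <- switch(spec$head,
                tanh2 = tanh(logits),
                softmax2 = softmaxC(logits),
                sigmoid1 = sigmoid(logits))
  list(out = out, logits = logits, cache = cache, state = state)
}

netBackward <- function(net, fw, dLogits) {
  if (net@variant == "M2") {
    back <- backwardTape(fw$cache$decPlan, net@params, fw$cache$dec, dLogits)
    grads <- back$grads
    lb <- convlstmBackward(net@params, fw$cache$lstm$caches, back$dX,
                           net@spec$latentWidth)
    for (k in names(lb$grads))
      grads[[k]] <- (grads[[k]] %||% 0) + lb$grads[[k]]
    for (t in seq_along(fw$cache$encs)) {
      eb <- backwardTape(fw$cache$encPlan, net@params, fw$cache$encs[[t]],
                         lb$dxs[[t]])
      for (k in names(eb$grads))
        grads[[k]] <- (grads[[k]] %||% 0) + eb$grads[[k]]
    }
    grads
  } else {
    backwardTape(fw$cache$plan, net@params, fw$cache$fwd, dLogits)$grads
  }
}

# Gradient of the loss with respect to the head logits, fused with the head
# activation. Returns list(loss, dLogits).
headLossGrad <- function(net, fw, target, mask = NULL) {
  out <- fw$out
  d <- dims4(out)
  if (net@spec$head == "tanh2") {
    r <- phaseLossGrad(out, target, mask)
    list(loss = r$loss, dLogits = r$grad * (1 - out^2))
  } else if (net@spec$head == "softmax2") {
    eps <- 1e-12
    loss <- -sum(as4(target) * log(out + eps)) / (d[1] * d[2] * d[4])
    list(loss = loss, dLogits = (out - as4(target)) / (d[1] * d[2] * d[4]))
  } else {
    # sigmoid1: weighted Hausdorff against per-sample point lists
    B <- d[4]
    loss <- 0
    dP <- array(0, d)
    for (b in seq_len(B)) {
      r <- weightedHausdorffGrad(matrix(out[, , 1, b], d[1], d[2]),
                                 target[[b]])
      loss <- loss + r$loss / B
      dP[, , 1, b] <- r$grad / B
    }
    list(loss = loss, dLogits = dP * out * (1 - out))
  }
}

# ---- training ----------------------------------------------------------------

sliceTarget <- function(targets, head, idx) {
  if (head == "sigmoid1") return(targets[idx])
  targets[, , , idx, drop = FALSE]
}

#' Train a network
#'
#' Mini-batch Adam training with a held-out validation split. Deterministic
#' for fixed seeds: sample order, initialization and batch composition are
#' all seeded, and all kernels are deterministic.
#'
#' @param net a \linkS4class{RotorNet}.
#' @param dataset a \linkS4class{RotorDataset} whose target kind matches the
#'   network head (phase for M1/M2/M3, ps_classmap for M1A, ps_coords for
#'   M1B).
#' @param epochs training epochs (default 12).
#' @param batchSize samples per batch (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param valFraction held-out validation fraction (default 0.05).
#' @param seed shuffling seed.
#' @param verbose print per-epoch losses.
#' @return the trained \linkS4class{RotorNet}; \code{net@state$history} holds
#'   per-epoch train/val losses.
#' @export
trainModel <- function(net, dataset, epochs = 12L, batchSize = 32L,
                       lr = 1e-3, valFraction = 0.05, seed = 1L,
                       verbose = TRUE) {
  kindNeeded <- switch(net@spec$head, tanh2 = "phase",
                       softmax2 = "ps_classmap", sigmoid1 = "ps_coords")
  if (dataset@spec@targetKind != kindNeeded)
    stop("dataset target kind '", dataset@spec@targetKind,
         "' does not match network head (needs '", kindNeeded, "')")
  X <- dataset@inputs
  targ <- dataset@targets[[1]]
  masks <- dataset@masks
  N <- dims4(X)[4]
  nval <- max(1L, floor(valFraction * N))
  perm <- withSeed(seed, sample.int(N))
  valIdx <- perm[seq_len(nval)]
  trIdx <- perm[-seq_len(nval)]
  opt <- adamInit(net@params)
  hist <- data.frame()
  params <- net@params
  state <- net@state
  for (ep in seq_len(epochs)) {
    ord <- withSeed(seed + ep, sample(trIdx))
    tot <- 0; nb <- 0
    for (s in seq(1L, length(ord), by = batchSize)) {
      idx <- ord[s:min(s + batchSize - 1L, length(ord))]
      xb <- X[, , , idx, drop = FALSE]
      tb <- sliceTarget(targ, net@spec$head, idx)
      mb <- if (is.null(masks) || !length(masks)) NULL else
        masks[, , idx, drop = FALSE]
      net@params <- params
      net@state <- state
      fw <- netForward(net, xb, train = TRUE)
      state <- fw$state
      hl <- headLossGrad(net, fw, tb, mb)
      grads <- netBackward(net, fw, hl$dLogits)
      r <- adamStep(params, grads, opt, lr)
      params <- r$params
      opt <- r$opt
      tot <- tot + hl$loss
      nb <- nb + 1
    }
    # validation in inference mode
    net@params <- params
    net@state <- state
    vloss <- 0; vb <- 0
    for (s in seq(1L, length(valIdx), by = batchSize)) {
      idx <- valIdx[s:min(s + batchSize - 1L, length(valIdx))]
      fw <- netForward(net, X[, , , idx, drop = FALSE], train = FALSE)
      hl <- headLossGrad(net, fw, sliceTarget(targ, net@spec$head, idx),
                         if (is.null(masks) || !length(masks)) NULL else
                           masks[, , idx, drop = FALSE])
      vloss <- vloss + hl$loss
      vb <- vb + 1
    }
    hist <- rbind(hist, data.frame(epoch = ep, train = tot / max(nb, 1),
                                   val = vloss / max(vb, 1)))
    if (verbose)
      message(sprintf("epoch %d: train %.5f, val %.5f", ep, tot / max(nb, 1),
                      vloss / max(vb, 1)))
  }
  net@params <- params
  state$history <- hist
  net@state <- state
  net
}

# ---- prediction --------------------------------------------------------------

#' Predict phase maps
#'
#' Runs a phase-head network (M1/M2/M3) in inference mode and decodes the
#' trigonometric output to angles.
#'
#' @param net a trained \linkS4class{RotorNet} with a phase head.
#' @param x input sample H x W x N_t, or batch H x W x N_t x B.
#' @return phase matrix H x W (or array H x W x B) in [-pi, pi).
#' @export
predictPhase <- function(net, x) {
  if (net@spec$head != "tanh2")
    stop("predictPhase requires a phase-head model (M1/M2/M3)")
  fw <- netForward(net, x, train = FALSE)
  out <- fw$out
  d <- dims4(out)
  ph <- wrapPhase(atan2(out[, , 2, , drop = FALSE], out[, , 1, , drop = FALSE]))
  dim(ph) <- c(d[1], d[2], d[4])
  if (d[4] == 1L) matrix(ph, d[1], d[2]) else ph
}

#' Predict phase singularities
#'
#' Direct route for M1A (class-map channel thresholded) and M1B (probability
#' map thresholded); indirect route for phase-head models (predicted phase
#' map passed through \code{\link{detectPS}}). Batch samples are reported as
#' consecutive frames of the returned set.
#'
#' @param net a trained \linkS4class{RotorNet}.
#' @param x input sample or batch.
#' @param threshold binarization threshold for the direct route.
#' @param weighted intensity-weighted centroids for the direct route.
#' @return a \linkS4class{PhaseSingularitySet}; \code{meta} route recorded in
#'   the \code{points} attribute "method".
#' @export
predictPS <- function(net, x, threshold = 0.5, weighted = TRUE) {
  if (net@spec$head == "tanh2") {
    ph <- predictPhase(net, x)
    ps <- detectPS(ph)
    attr(ps@points, "method") <- paste0(net@variant, "-indirect")
    return(ps)
  }
  fw <- netForward(net, x, train = FALSE)
  out <- fw$out
  d <- dims4(out)
  prob <- if (net@spec$head == "softmax2") out[, , 2, , drop = FALSE]
          else out[, , 1, , drop = FALSE]
  dim(prob) <- c(d[1], d[2], d[4])
  ps <- psFromProbability(prob, threshold, weighted = weighted)
  attr(ps@points, "method") <- paste0(net@variant, "-direct")
  ps
}
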