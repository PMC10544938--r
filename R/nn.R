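# Minimal CNN toolkit backing the trainable detector and restorer contracts.
#
# Tensors are numeric arrays dim (C, H, W); all layers run single-sample
# (batching is a loop at the training level, matching the tiny problem sizes
# the package trains at). Each layer is a list carrying parameters plus
# forward/backward semantics dispatched by type.

nnInit <- function(dims, fanIn, gain = 1) {
  array(rnorm(prod(dims), 0, gain * sqrt(2 / fanIn)), dim = dims)
}

nnConv <- function(inC, outC, k = 3L, stride = 1L, pad = 1L,
                   activation = c("lrelu", "relu", "sigmoid", "tanh",
                                  "linear")) {
  activation <- match.arg(activation)
  list(type = "conv",
       w = nnInit(c(outC, inC, k, k), fanIn = inC * k * k),
       b = numeric(outC), stride = as.integer(stride), pad = as.integer(pad),
       activation = activation)
}

nnAct <- function(z, act) {
  switch(act,
         lrelu = ifelse(z > 0, z, 0.2 * z),
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         linear = z)
}

nnActGrad <- function(z, a, act) {
  switch(act,
         lrelu = ifelse(z > 0, 1, 0.2),
         relu = (z > 0) * 1,
         sigmoid = a * (1 - a),
         tanh = 1 - a^2,
         linear = 1)
}

nnConvForward <- function(layer, x) {
  z <- convForwardCpp(x, layer$w, layer$b, layer$stride, layer$pad)
  a <- array(nnAct(z, layer$activation), dim = dim(z))
  list(out = a, cache = list(x = x, z = z, a = a))
}

nnConvBackward <- function(layer, cache, gout) {
  gz <- array(gout * nnActGrad(cache$z, cache$a, layer$activation),
              dim = dim(cache$z))
  g <- convBackwardCpp(cache$x, layer$w, gz, layer$stride, layer$pad)
  list(gin = g$gx, gw = g$gw, gb = g$gb)
}

# Adam step applied in place on a layer list; state kept alongside.
nnMakeOpt <- function(layers, type = c("adam", "sgd"), lr = 2e-4,
                      beta1 = 0.5, beta2 = 0.999, momentum = 0.9,
                      weightDecay = 0) {
  type <- match.arg(type)
  state <- lapply(layers, function(l) {
    if (is.null(l$w)) return(NULL)
    list(mw = array(0, dim(l$w)), vw = array(0, dim(l$w)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b)))
  })
  list(type = type, lr = lr, beta1 = beta1, beta2 = beta2,
       momentum = momentum, weightDecay = weightDecay, t = 0L, state = state)
}

nnOptStep <- function(opt, layers, grads) {
  opt$t <- opt$t + 1L
  for (i in seq_along(layers)) {
    if (is.null(layers[[i]]$w) || is.null(grads[[i]])) next
    gw <- grads[[i]]$gw + opt$weightDecay * layers[[i]]$w
    gb <- grads[[i]]$gb
    s <- opt$state[[i]]
    if (opt$type == "adam") {
      s$mw <- opt$beta1 * s$mw + (1 - opt$beta1) * gw
      s$vw <- opt$beta2 * s$vw + (1 - opt$beta2) * gw^2
      s$mb <- opt$beta1 * s$mb + (1 - opt$beta1) * gb
      s$vb <- opt$beta2 * s$vb + (1 - opt$beta2) * gb^2
      bc1 <- 1 - opt$beta1^opt$t; bc2 <- 1 - opt$beta2^opt$t
      layers[[i]]$w <- layers[[i]]$w -
        opt$lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + 1e-8)
      layers[[i]]$b <- layers[[i]]$b -
        opt$lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + 1e-8)
    } else {
      s$mw <- opt$momentum * s$mw + gw
      s$mb <- opt$momentum * s$mb + gb
      layers[[i]]$w <- layers[[i]]$w - opt$lr * s$mw
      layers[[i]]$b <- layers[[i]]$b - opt$lr * s$mb
    }
    opt$state[[i]] <- s
  }
  list(opt = opt, layers = layers)
}

# Binary cross-entropy on sigmoid activations, elementwise mean, with the
# gradient taken w.r.t. the activation.
nnBCE <- function(a, target) {
  a <- clamp(a, 1e-7, 1 - 1e-7)
  loss <- -mean(target * log(a) + (1 - target) * log(1 - a))
  grad <- (-(target / a) + (1 - target) / (1 - a)) / length(a)
  list(loss = loss, grad = array(grad, dim = dim(a) %||% length(a)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 8-bit H x W x 3 image <-> (C,H,W) float tensor in [0, 1]
imageToTensor <- function(pixels) {
  d <- dim(pixels)
  aperm(array(as.numeric(pixels) / 255, d), c(3L, 1L, 2L))
}

tensorToImage <- function(t) {
  quantize8(aperm(t, c(2L, 3L, 1L)) * 255)
}

# Output spatial size of a conv schedule (list of k/s/p) for square input.
convScheduleSizes <- function(size, schedule) {
  out <- integer(length(schedule))
  cur <- size
  for (i in seq_along(schedule)) {
    s <- schedule[[i]]
    cur <- (cur + 2L * s$p - s$k) %/% s$s + 1L
    out[i] <- cur
  }
  out
}

# Receptive field of the final unit of a conv schedule.
convScheduleReceptiveField <- function(schedule) {
  rf <- 1L; jump <- 1L
  for (s in schedule) {
    rf <- rf + (s$k - 1L) * jump
    jump <- jump * s$s
  }
  rf
}
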