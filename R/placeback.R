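NT_TOKENS <- c("A", "C", "G", "T", "N")

# Map a nucleotide string to integer tokens 1..5; errors name the first
# offending position.
tokenize_seq <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  tok <- match(ch, NT_TOKENS)
  if (anyNA(tok)) {
    i <- which(is.na(tok))[1]
    stop("character '", ch[i], "' at position ", i,
         " is outside the {A,C,G,T,N} alphabet")
  }
  tok
}

#' Configuration of a Place-Back model
#'
#' A Place-Back network maps a (disrupted promoter, query) pair to 400
#' per-base probabilities that each position belonged to the query's
#' original location. The promoter branch is token embedding + sinusoidal
#' positional encoding, a same-padded convolution, a strided convolution
#' compressing the sequence by `compression_factor`, a transformer encoder,
#' nearest-neighbour decompression with a convolution, and a linear
#' projection; the query branch is embedding + bidirectional LSTM; the two
#' are fused by scaled dot-product attention, max-pooled over the query
#' axis, and passed through a per-position sigmoid.
#'
#' Two presets are provided: `test_scale` (~15K parameters, trains on a CPU
#' in minutes) and `paper_scale` (~5.1M parameters, matching the published
#' order of magnitude of ~6M); any field can be overridden.
#'
#' @param msrl Model-specific rewriting length, 5 or 40 bp.
#' @param preset "test_scale" or "paper_scale".
#' @param seed Integer seed for weight initialization.
#' @param ... Overrides for individual architecture fields
#'   (`embedding_dim`, `conv_channels` (length 2), `conv_kernel`,
#'   `compression_factor`, `n_transformer_layers`, `n_heads`, `ffn_dim`,
#'   `lstm_hidden`, `fusion_dim`, `promoter_length`, `query_max`).
#' @return A `placeback_config` list.
#' @export
placeback_config <- function(msrl, preset = c("test_scale", "paper_scale"),
                             seed = 1L, ...) {
  stopifnot(msrl %in% c(5, 40))
  preset <- match.arg(preset)
  cfg <- if (preset == "test_scale") {
    list(embedding_dim = 8L, conv_channels = c(16L, 24L), conv_kernel = 7L,
         compression_factor = 4L, n_transformer_layers = 1L, n_heads = 2L,
         ffn_dim = 48L, lstm_hidden = 8L, fusion_dim = 16L)
  } else {
    list(embedding_dim = 128L, conv_channels = c(256L, 256L),
         conv_kernel = 7L, compression_factor = 4L,
         n_transformer_layers = 4L, n_heads = 8L, ffn_dim = 1024L,
         lstm_hidden = 256L, fusion_dim = 256L)
  }
  cfg$msrl <- as.integer(msrl)
  cfg$preset <- preset
  cfg$seed <- as.integer(seed)
  cfg$promoter_length <- 400L
  cfg$query_max <- 64L
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (cfg$promoter_length %% cfg$compression_factor != 0L)
    stop("compression_factor must divide promoter_length so decompression ",
         "restores a ", cfg$promoter_length, "-length output")
  if (cfg$conv_channels[2] %% cfg$n_heads != 0L)
    stop("n_heads must divide the transformer width (conv_channels[2])")
  if (cfg$conv_kernel %% 2L != 1L) stop("conv_kernel must be odd")
  structure(cfg, class = "placeback_config")
}

#' Build a seeded Place-Back model
#'
#' Instantiates all weights deterministically from the config seed; two
#' builds from the same config are bitwise identical.
#'
#' @param config A [placeback_config()].
#' @return An object of class `placeback_model`.
#' @export
build_placeback <- function(config) {
  stopifnot(inherits(config, "placeback_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  E <- config$embedding_dim
  C1 <- config$conv_channels[1]; C2 <- config$conv_channels[2]
  k <- config$conv_kernel; f <- config$compression_factor
  H <- config$lstm_hidden; Df <- config$fusion_dim
  p <- list(
    emb_p = pr_new("emb_p", 5L, E),
    emb_q = pr_new("emb_q", 5L, E),
    conv1_W = pr_new("conv1_W", k * E, C1), conv1_b = pr_new("conv1_b", 1L, C1, "zeros"),
    conv2_W = pr_new("conv2_W", f * C1, C2), conv2_b = pr_new("conv2_b", 1L, C2, "zeros"),
    deconv_W = pr_new("deconv_W", k * C2, C1), deconv_b = pr_new("deconv_b", 1L, C1, "zeros"),
    proj_W = pr_new("proj_W", C1, Df), proj_b = pr_new("proj_b", 1L, Df, "zeros"),
    qproj_W = pr_new("qproj_W", 2L * H, Df), qproj_b = pr_new("qproj_b", 1L, Df, "zeros"),
    fuse_gain = pr_new("fuse_gain", 1L, 1L, "ones"),
    fuse_bias = pr_new("fuse_bias", 1L, 1L, "zeros")
  )
  for (l in seq_len(config$n_transformer_layers)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0("tf", l, "_", nm)]] <- pr_new(paste0("tf", l, "_", nm), C2, C2)
    for (nm in c("bq", "bk", "bv", "bo"))
      p[[paste0("tf", l, "_", nm)]] <- pr_new(paste0("tf", l, "_", nm), 1L, C2, "zeros")
    p[[paste0("tf", l, "_ln1_g")]] <- pr_new("ln1_g", 1L, C2, "ones")
    p[[paste0("tf", l, "_ln1_b")]] <- pr_new("ln1_b", 1L, C2, "zeros")
    p[[paste0("tf", l, "_f1_W")]] <- pr_new("f1_W", C2, config$ffn_dim)
    p[[paste0("tf", l, "_f1_b")]] <- pr_new("f1_b", 1L, config$ffn_dim, "zeros")
    p[[paste0("tf", l, "_f2_W")]] <- pr_new("f2_W", config$ffn_dim, C2)
    p[[paste0("tf", l, "_f2_b")]] <- pr_new("f2_b", 1L, C2, "zeros")
    p[[paste0("tf", l, "_ln2_g")]] <- pr_new("ln2_g", 1L, C2, "ones")
    p[[paste0("tf", l, "_ln2_b")]] <- pr_new("ln2_b", 1L, C2, "zeros")
  }
  for (dir in c("f", "b")) {
    p[[paste0("lstm_", dir, "_Wx")]] <- pr_new("lstm_Wx", E, 4L * H)
    p[[paste0("lstm_", dir, "_Wh")]] <- pr_new("lstm_Wh", H, 4L * H)
    b <- pr_new("lstm_b", 1L, 4L * H, "zeros")
    b$value[1, (H + 1):(2 * H)] <- 1  # forget-gate bias
    p[[paste0("lstm_", dir, "_b")]] <- b
  }
  structure(list(config = config, params = p,
                 model_id = sprintf("placeback_msrl%d_%s_seed%d",
                                    config$msrl, config$preset, config$seed),
                 steps_trained = 0L),
            class = "placeback_model")
}

#' @export
print.placeback_model <- function(x, ...) {
  cat(sprintf("placeback_model %s: MSRL %d bp, %s preset, %s parameters, %d training steps\n",
              x$model_id, x$config$msrl, x$config$preset,
              format(n_parameters(x), big.mark = ","), x$steps_trained))
  invisible(x)
}

#' Number of trainable parameters of a model
#'
#' @param model A `placeback_model` or `determiner_model`.
#' @return Integer count of trainable scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(pr) length(pr$value), numeric(1)))
}

# batched bidirectional LSTM over padded query tokens; returns per-timestep
# node lists for both directions (each node B x H)
pb_query_lstm <- function(model, tp, qtok, qlens) {
  cfg <- model$config; p <- model$params
  H <- cfg$lstm_hidden
  B <- nrow(qtok)
  Tq <- ncol(qtok)
  run_dir <- function(dir, order) {
    Wx <- t_param(tp, p[[paste0("lstm_", dir, "_Wx")]])
    Wh <- t_param(tp, p[[paste0("lstm_", dir, "_Wh")]])
    bb <- t_param(tp, p[[paste0("lstm_", dir, "_b")]])
    h <- t_const(tp, matrix(0, B, H))
    cc <- t_const(tp, matrix(0, B, H))
    outs <- vector("list", Tq)
    for (t in order) {
      x <- t_embed(tp, p$emb_q, qtok[, t])
      gates <- t_add(tp, t_add(tp, t_mm(tp, x, Wx), t_mm(tp, h, Wh)), bb)
      ig <- t_sigmoid(tp, t_slice_cols(tp, gates, 1:H))
      fg <- t_sigmoid(tp, t_slice_cols(tp, gates, (H + 1):(2 * H)))
      og <- t_sigmoid(tp, t_slice_cols(tp, gates, (2 * H + 1):(3 * H)))
      gg <- t_tanh(tp, t_slice_cols(tp, gates, (3 * H + 1):(4 * H)))
      c_new <- t_add(tp, t_mul(tp, fg, cc), t_mul(tp, ig, gg))
      h_new <- t_mul(tp, og, t_tanh(tp, c_new))
      m <- as.numeric(t <= qlens)        # mask: hold state past query end
      if (all(m == 1)) {
        h <- h_new; cc <- c_new
      } else {
        h <- t_add(tp, t_rowscale(tp, h_new, m), t_rowscale(tp, h, 1 - m))
        cc <- t_add(tp, t_rowscale(tp, c_new, m), t_rowscale(tp, cc, 1 - m))
      }
      outs[[t]] <- h
    }
    outs
  }
  list(fwd = run_dir("f", seq_len(Tq)), bwd = run_dir("b", rev(seq_len(Tq))))
}

# promoter branch for one sample: tokens -> 400 x fusion_dim representation
pb_promoter_branch <- function(model, tp, ptok) {
  cfg <- model$config; p <- model$params
  P <- cfg$promoter_length
  k <- cfg$conv_kernel; f <- cfg$compression_factor
  C2 <- cfg$conv_channels[2]; nh <- cfg$n_heads; dh <- C2 %/% nh
  pe <- positional_encoding(P, cfg$embedding_dim)
  x <- t_add_const(tp, t_embed(tp, p$emb_p, ptok), pe)
  x <- t_relu(tp, t_add(tp, t_mm(tp, t_unfold(tp, t_pad_rows(tp, x, (k - 1L) %/% 2L,
        (k - 1L) %/% 2L), k, 1L), t_param(tp, p$conv1_W)), t_param(tp, p$conv1_b)))
  x <- t_relu(tp, t_add(tp, t_mm(tp, t_unfold(tp, x, f, f),
        t_param(tp, p$conv2_W)), t_param(tp, p$conv2_b)))
  for (l in seq_len(cfg$n_transformer_layers)) {
    gp <- function(nm) t_param(tp, p[[paste0("tf", l, "_", nm)]])
    Q <- t_add(tp, t_mm(tp, x, gp("Wq")), gp("bq"))
    K <- t_add(tp, t_mm(tp, x, gp("Wk")), gp("bk"))
    V <- t_add(tp, t_mm(tp, x, gp("Wv")), gp("bv"))
    heads <- vector("list", nh)
    for (hh in seq_len(nh)) {
      cols <- ((hh - 1L) * dh + 1L):(hh * dh)
      Qh <- t_slice_cols(tp, Q, cols)
      Kh <- t_slice_cols(tp, K, cols)
      Vh <- t_slice_cols(tp, V, cols)
      A <- t_softmax_rows(tp, t_scale(tp, t_mm(tp, Qh, t_transpose(tp, Kh)),
                                      1 / sqrt(dh)))
      heads[[hh]] <- t_mm(tp, A, Vh)
    }
    Hc <- Reduce(function(a, b) t_cbind(tp, a, b), heads)
    attn <- t_add(tp, t_mm(tp, Hc, gp("Wo")), gp("bo"))
    x <- t_layernorm(tp, t_add(tp, x, attn), gp("ln1_g"), gp("ln1_b"))
    ff <- t_add(tp, t_mm(tp, t_relu(tp, t_add(tp, t_mm(tp, x, gp("f1_W")),
          gp("f1_b"))), gp("f2_W")), gp("f2_b"))
    x <- t_layernorm(tp, t_add(tp, x, ff), gp("ln2_g"), gp("ln2_b"))
  }
  x <- t_rows_repeat(tp, x, f)
  x <- t_relu(tp, t_add(tp, t_mm(tp, t_unfold(tp, t_pad_rows(tp, x,
        (k - 1L) %/% 2L, (k - 1L) %/% 2L), k, 1L), t_param(tp, p$deconv_W)),
        t_param(tp, p$deconv_b)))
  t_add(tp, t_mm(tp, x, t_param(tp, p$proj_W)), t_param(tp, p$proj_b))
}

# full forward for a batch: returns list of per-sample logit nodes (400 x 1)
pb_forward <- function(model, tp, ptoks, qtoks, qlens) {
  cfg <- model$config; p <- model$params
  B <- length(ptoks)
  lstm <- pb_query_lstm(model, tp, qtoks, qlens)
  qW <- t_param(tp, p$qproj_W); qb <- t_param(tp, p$qproj_b)
  gain <- t_param(tp, p$fuse_gain); bias <- t_param(tp, p$fuse_bias)
  logits <- vector("list", B)
  for (i in seq_len(B)) {
    Pm <- pb_promoter_branch(model, tp, ptoks[[i]])
    take <- seq_len(qlens[i])
    Qm <- t_cbind(tp, t_stack_row(tp, lstm$fwd, i, take),
                  t_stack_row(tp, lstm$bwd, i, take))
    Qm <- t_add(tp, t_mm(tp, Qm, qW), qb)
    sc <- t_scale(tp, t_mm(tp, Pm, t_transpose(tp, Qm)),
                  1 / sqrt(cfg$fusion_dim))
    mx <- t_max_rows(tp, sc)
    logits[[i]] <- t_add(tp, t_mm(tp, mx, gain), bias)
  }
  logits
}

# tokenize a batch of training samples for pb_forward
pb_tokenize_batch <- function(samples, query_max = 64L) {
  B <- length(samples)
  ptoks <- lapply(samples, function(s) tokenize_seq(s$disrupted_promoter))
  qlens <- vapply(samples, function(s) nchar(s$query), integer(1))
  qtoks <- matrix(5L, B, max(qlens))   # pad with N tokens (masked)
  for (i in seq_len(B)) {
    qtoks[i, seq_len(qlens[i])] <- tokenize_seq(samples[[i]]$query)
  }
  list(ptoks = ptoks, qtoks = qtoks, qlens = qlens)
}

#' Predict a per-base placement probability curve
#'
#' Runs the Place-Back model in inference mode on one promoter/query pair.
#' Deterministic for a fixed model (no dropout is used anywhere).
#'
#' @param model A `placeback_model`.
#' @param promoter Nucleotide string of the configured promoter length
#'   (400 bp) over \{A,C,G,T,N\}.
#' @param query Nucleotide string of 8-64 bp.
#' @return A `prediction_curve`: list with `probs` (400 values in \[0,1\]),
#'   `model_id` and `msrl`.
#' @export
predict_placeback <- function(model, promoter, query) {
  stopifnot(inherits(model, "placeback_model"))
  cfg <- model$config
  if (nchar(promoter) != cfg$promoter_length)
    stop("promoter must be exactly ", cfg$promoter_length, " bases")
  if (nchar(query) < 8 || nchar(query) > cfg$query_max)
    stop("query length must be in [8, ", cfg$query_max, "]")
  tp <- tape_new(grad_on = FALSE)
  ptok <- tokenize_seq(promoter)
  qtok <- matrix(tokenize_seq(query), nrow = 1L)
  z <- pb_forward(model, tp, list(ptok), qtok, nchar(query))[[1]]
  probs <- as.vector(1 / (1 + exp(-tp_val(tp, z))))
  structure(list(probs = probs, model_id = model$model_id, msrl = cfg$msrl),
            class = "prediction_curve")
}

#' @export
print.prediction_curve <- function(x, ...) {
  cat(sprintf("prediction_curve from %s (MSRL %d): peak %.3f at position %d\n",
              x$model_id, x$msrl, max(x$probs), which.max(x$probs) - 1L))
  invisible(x)
}

#' Train a Place-Back model
#'
#' Minimizes mean per-position binary cross-entropy between the sigmoid
#' output and the 400-length binary rewrite-window label, with Adam.
#' Parameters are updated in place (model objects hold environments); the
#' updated model is also returned with a training trace.
#'
#' @param model A `placeback_model`; its config `msrl` must match the
#'   stream's.
#' @param stream A [sample_stream()] or a fixed list of `training_sample`s
#'   (the latter is trained as a full batch every step, e.g. for
#'   memorization checks).
#' @param steps Number of optimizer steps.
#' @param lr Adam learning rate (default 3e-3).
#' @param eval_every Cadence (in steps) for recording base-level
#'   precision/recall on `eval_samples`; 0 disables.
#' @param eval_samples Optional held-out samples for the trace metrics.
#' @param verbose Print the trace as it is recorded.
#' @return The model, with a `trace` data frame (`step`, `loss`, and when
#'   evaluated, `precision`, `recall`) stored in `model$trace`.
#' @export
train_placeback <- function(model, stream, steps, lr = 3e-3,
                            eval_every = 0L, eval_samples = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(model, "placeback_model"))
  fixed <- is.list(stream) && !inherits(stream, "sample_stream")
  if (fixed) {
    bad <- vapply(stream, function(s) s$msrl != model$config$msrl, logical(1))
    if (any(bad)) stop("stream msrl does not match model config msrl")
    toks <- pb_tokenize_batch(stream, model$config$query_max)
    labels <- lapply(stream, function(s)
      matrix(sample_label(s, model$config$promoter_length), ncol = 1L))
  }
  opt <- adam_new(model$params, lr = lr)
  trace <- list()
  for (step in seq_len(steps)) {
    if (!fixed) {
      batch <- stream$next_batch()
      bad <- vapply(batch, function(s) s$msrl != model$config$msrl, logical(1))
      if (any(bad)) stop("stream msrl does not match model config msrl")
      toks <- pb_tokenize_batch(batch, model$config$query_max)
      labels <- lapply(batch, function(s)
        matrix(sample_label(s, model$config$promoter_length), ncol = 1L))
    }
    tp <- tape_new(grad_on = TRUE)
    logits <- pb_forward(model, tp, toks$ptoks, toks$qtoks, toks$qlens)
    losses <- mapply(function(z, y) t_bce_logits(tp, z, y), logits, labels)
    total <- Reduce(function(a, b) t_add(tp, a, b), losses)
    total <- t_scale(tp, total, 1 / length(losses))
    loss <- as.numeric(tp_val(tp, total))
    if (!is.finite(loss))
      stop("non-finite loss at step ", step, "; lower the learning rate")
    backward(tp, total)
    adam_step(opt)
    row <- data.frame(step = step, loss = loss,
                      precision = NA_real_, recall = NA_real_)
    if (eval_every > 0 && !is.null(eval_samples) &&
        (step %% eval_every == 0L || step == steps)) {
      m <- evaluate_placeback(model, eval_samples)
      row$precision <- m["precision"]; row$recall <- m["recall"]
    }
    if (verbose) message(sprintf("step %d loss %.4f", step, loss))
    trace[[step]] <- row
  }
  model$steps_trained <- model$steps_trained + steps
  model$trace <- do.call(rbind, trace)
  model
}

#' Base-level precision and recall of a Place-Back model
#'
#' Thresholds each predicted curve at `threshold` and scores the resulting
#' positive positions against the sample's rewrite window. Precision is
#' macro-averaged over samples with at least one positive prediction (curves
#' with none are excluded); recall is averaged over all samples.
#'
#' @param model A `placeback_model`.
#' @param samples List of `training_sample`s with the model's MSRL.
#' @param threshold Probability threshold for a positive call (default 0.5).
#' @return Named vector with `precision`, `recall`, and
#'   `n_with_positives`.
#' @export
evaluate_placeback <- function(model, samples, threshold = 0.5) {
  stopifnot(length(samples) >= 1)
  precs <- numeric(0); recs <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (s$msrl != model$config$msrl)
      stop("sample msrl (", s$msrl, ") does not match model msrl (",
           model$config$msrl, ")")
    curve <- predict_placeback(model, s$disrupted_promoter, s$query)
    pred <- which(curve$probs >= threshold) - 1L
    pr <- base_precision_recall(pred, s$rewrite_window, s$msrl)
    if (!is.na(pr["precision"])) precs <- c(precs, pr["precision"])
    recs[i] <- pr["recall"]
  }
  c(precision = if (length(precs)) mean(precs) else NA_real_,
    recall = mean(recs),
    n_with_positives = length(precs))
}
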