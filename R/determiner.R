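STACK_MSRL_ORDER <- c(5L, 5L, 40L, 40L)

#' Stack of four Place-Back prediction curves
#'
#' The Determiner input: a 4 x 400 matrix of per-base probabilities in the
#' fixed row order (5 bp model A, 5 bp model B, 40 bp model A, 40 bp model
#' B).
#'
#' @param curves 4 x 400 numeric matrix with values in \[0, 1\], or a list
#'   of four `prediction_curve`s in that MSRL order.
#' @param promoter_id,query Optional provenance fields.
#' @return An object of class `curve_stack`.
#' @export
curve_stack <- function(curves, promoter_id = NA_character_,
                        query = NA_character_) {
  if (is.list(curves) && all(vapply(curves, inherits, logical(1),
                                    "prediction_curve"))) {
    msrls <- vapply(curves, function(cu) cu$msrl, integer(1))
    if (!identical(msrls, STACK_MSRL_ORDER))
      stop("curve list must have MSRL order (5, 5, 40, 40)")
    curves <- do.call(rbind, lapply(curves, function(cu) cu$probs))
  }
  if (!is.matrix(curves) || nrow(curves) != 4L)
    stop("curve stack must be a 4 x promoter_length matrix")
  if (any(curves < 0 | curves > 1))
    stop("curve values must lie in [0, 1]")
  structure(list(curves = curves, msrl_order = STACK_MSRL_ORDER,
                 promoter_id = promoter_id, query = query),
            class = "curve_stack")
}

#' Configuration of a Determiner model
#'
#' A Determiner classifies, from the 4 x 400 stack of Place-Back curves,
#' (1) the rewrite length the sample was generated with (5 vs 40 bp) and
#' (2) the original query position region, one of ten 40 bp bins. Two
#' architecture families are provided: `cnn` (two strided convolutions over
#' the position axis, then dense layers) and `lstm` (position-axis
#' average pooling, a bidirectional LSTM, then dense layers); five width
#' variants of each make up the 10-member ensemble.
#'
#' @param arch "cnn" or "lstm".
#' @param variant Width variant 1-5.
#' @param preset "test_scale" (CPU-seconds training) or "paper_scale".
#' @param seed Integer seed for weight initialization.
#' @return A `determiner_config` list.
#' @export
determiner_config <- function(arch = c("cnn", "lstm"), variant = 1L,
                              preset = c("test_scale", "paper_scale"),
                              seed = 1L) {
  arch <- match.arg(arch)
  preset <- match.arg(preset)
  stopifnot(variant %in% 1:5)
  mult <- if (preset == "test_scale") 1L else 16L
  widths <- list(
    cnn = list(c1 = c(8L, 12L, 16L, 10L, 14L),
               c2 = c(12L, 16L, 20L, 14L, 18L),
               hidden = c(16L, 24L, 32L, 20L, 28L)),
    lstm = list(hidden = c(8L, 12L, 16L, 10L, 14L),
                dense = c(16L, 24L, 32L, 20L, 28L)))
  cfg <- list(arch = arch, variant = as.integer(variant), preset = preset,
              seed = as.integer(seed), promoter_length = 400L,
              n_regions = 10L)
  if (arch == "cnn") {
    cfg$c1 <- widths$cnn$c1[variant] * mult
    cfg$c2 <- widths$cnn$c2[variant] * mult
    cfg$hidden <- widths$cnn$hidden[variant] * mult
    cfg$k1 <- 8L; cfg$s1 <- 4L; cfg$k2 <- 5L; cfg$s2 <- 5L
  } else {
    cfg$pool <- 10L
    cfg$hidden <- widths$lstm$hidden[variant] * mult
    cfg$dense <- widths$lstm$dense[variant] * mult
  }
  structure(cfg, class = "determiner_config")
}

#' Build a seeded Determiner model
#'
#' @param config A [determiner_config()].
#' @return An object of class `determiner_model`.
#' @export
build_determiner <- function(config) {
  stopifnot(inherits(config, "determiner_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  p <- list()
  if (config$arch == "cnn") {
    p$conv1_W <- pr_new("conv1_W", config$k1 * 4L, config$c1)
    p$conv1_b <- pr_new("conv1_b", 1L, config$c1, "zeros")
    p$conv2_W <- pr_new("conv2_W", config$k2 * config$c1, config$c2)
    p$conv2_b <- pr_new("conv2_b", 1L, config$c2, "zeros")
    flat <- 20L * config$c2
    p$d1_W <- pr_new("d1_W", flat, config$hidden)
    p$d1_b <- pr_new("d1_b", 1L, config$hidden, "zeros")
    top <- config$hidden
  } else {
    H <- config$hidden
    for (dir in c("f", "b")) {
      p[[paste0("lstm_", dir, "_Wx")]] <- pr_new("lstm_Wx", 4L, 4L * H)
      p[[paste0("lstm_", dir, "_Wh")]] <- pr_new("lstm_Wh", H, 4L * H)
      b <- pr_new("lstm_b", 1L, 4L * H, "zeros")
      b$value[1, (H + 1):(2 * H)] <- 1
      p[[paste0("lstm_", dir, "_b")]] <- b
    }
    p$d1_W <- pr_new("d1_W", 2L * H, config$dense)
    p$d1_b <- pr_new("d1_b", 1L, config$dense, "zeros")
    top <- config$dense
  }
  p$msrl_W <- pr_new("msrl_W", top, 2L)
  p$msrl_b <- pr_new("msrl_b", 1L, 2L, "zeros")
  p$region_W <- pr_new("region_W", top, 10L)
  p$region_b <- pr_new("region_b", 1L, 10L, "zeros")
  structure(list(config = config, params = p,
                 model_id = sprintf("determiner_%s_v%d_%s_seed%d",
                                    config$arch, config$variant,
                                    config$preset, config$seed),
                 steps_trained = 0L),
            class = "determiner_model")
}

#' @export
print.determiner_model <- function(x, ...) {
  cat(sprintf("determiner_model %s: %s parameters, %d training steps\n",
              x$model_id, format(n_parameters(x), big.mark = ","),
              x$steps_trained))
  invisible(x)
}

# forward pass to the two logit heads for one 400 x 4 input matrix
det_forward_one <- function(model, tp, X) {
  cfg <- model$config; p <- model$params
  x <- t_const(tp, X)
  if (cfg$arch == "cnn") {
    x <- t_pad_rows(tp, x, 2L, 2L)
    x <- t_relu(tp, t_add(tp, t_mm(tp, t_unfold(tp, x, cfg$k1, cfg$s1),
          t_param(tp, p$conv1_W)), t_param(tp, p$conv1_b)))
    x <- t_relu(tp, t_add(tp, t_mm(tp, t_unfold(tp, x, cfg$k2, cfg$s2),
          t_param(tp, p$conv2_W)), t_param(tp, p$conv2_b)))
    x <- t_flatten_row(tp, x)
  } else {
    x <- t_avgpool_rows(tp, x, cfg$pool)      # 40 x 4
    H <- cfg$hidden
    run_dir <- function(dir, order) {
      Wx <- t_param(tp, p[[paste0("lstm_", dir, "_Wx")]])
      Wh <- t_param(tp, p[[paste0("lstm_", dir, "_Wh")]])
      bb <- t_param(tp, p[[paste0("lstm_", dir, "_b")]])
      h <- t_const(tp, matrix(0, 1L, H)); cc <- h
      for (t in order) {
        xt <- t_slice_rows(tp, x, t)
        gates <- t_add(tp, t_add(tp, t_mm(tp, xt, Wx), t_mm(tp, h, Wh)), bb)
        ig <- t_sigmoid(tp, t_slice_cols(tp, gates, 1:H))
        fg <- t_sigmoid(tp, t_slice_cols(tp, gates, (H + 1):(2 * H)))
        og <- t_sigmoid(tp, t_slice_cols(tp, gates, (2 * H + 1):(3 * H)))
        gg <- t_tanh(tp, t_slice_cols(tp, gates, (3 * H + 1):(4 * H)))
        cc <- t_add(tp, t_mul(tp, fg, cc), t_mul(tp, ig, gg))
        h <- t_mul(tp, og, t_tanh(tp, cc))
      }
      h
    }
    x <- t_cbind(tp, run_dir("f", 1:40), run_dir("b", 40:1))
  }
  x <- t_relu(tp, t_add(tp, t_mm(tp, x, t_param(tp, p$d1_W)),
                        t_param(tp, p$d1_b)))
  list(msrl = t_add(tp, t_mm(tp, x, t_param(tp, p$msrl_W)),
                    t_param(tp, p$msrl_b)),
       region = t_add(tp, t_mm(tp, x, t_param(tp, p$region_W)),
                      t_param(tp, p$region_b)))
}

#' Classify rewrite length and insertion region from a curve stack
#'
#' Runs one Determiner on a 4 x 400 stack and returns the two softmax heads,
#' their argmax classes (ties broken toward the lower class index), and the
#' Match flag computed by [is_match()].
#'
#' @param model A `determiner_model`.
#' @param stack A [curve_stack()].
#' @param peak_threshold Peak threshold passed to [is_match()].
#' @return A `determiner_output`: list with `msrl_probs` (2-vector, sums to
#'   1), `region_probs` (10-vector, sums to 1), `msrl_pred` (5 or 40),
#'   `region_pred` (1-10), `match` (logical).
#' @export
predict_determiner <- function(model, stack, peak_threshold = 0.5) {
  stopifnot(inherits(model, "determiner_model"))
  if (!inherits(stack, "curve_stack")) stop("stack must be a curve_stack")
  if (ncol(stack$curves) != model$config$promoter_length)
    stop("stack has ", ncol(stack$curves), " positions; expected ",
         model$config$promoter_length)
  tp <- tape_new(grad_on = FALSE)
  heads <- det_forward_one(model, tp, t(stack$curves))
  sm <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  msrl_probs <- as.vector(sm(tp_val(tp, heads$msrl)))
  region_probs <- as.vector(sm(tp_val(tp, heads$region)))
  out <- structure(list(
    msrl_probs = stats::setNames(msrl_probs, c("5", "40")),
    region_probs = region_probs,
    msrl_pred = c(5L, 40L)[which.max(msrl_probs)],
    region_pred = which.max(region_probs),
    match = NA), class = "determiner_output")
  out$match <- is_match(out, stack, peak_threshold)
  out
}

#' Internal-consistency "Match" flag
#'
#' A Determiner decision is a Match when the Place-Back curves of the
#' selected rewrite length show a significant peak inside the predicted
#' region: the maximum, over the region's 40 positions, of the element-wise
#' maximum of the two selected-MSRL curves reaches `peak_threshold`.
#'
#' @param output A `determiner_output`.
#' @param stack The [curve_stack()] the output was computed from.
#' @param peak_threshold Absolute probability threshold (default 0.5).
#' @return Logical; monotone non-increasing in `peak_threshold`.
#' @export
is_match <- function(output, stack, peak_threshold = 0.5) {
  sel <- which(stack$msrl_order == output$msrl_pred)
  r <- output$region_pred
  bin_width <- ncol(stack$curves) %/% length(output$region_probs)
  cols <- ((r - 1L) * bin_width + 1L):(r * bin_width)
  peak <- max(pmax(stack$curves[sel[1], cols], stack$curves[sel[2], cols]))
  peak >= peak_threshold
}

#' Build the 10-member Determiner ensemble
#'
#' Five CNN and five LSTM width variants, each with its own seed, matching
#' the design of a heterogeneous consensus ensemble.
#'
#' @param preset "test_scale" or "paper_scale".
#' @param seed Base seed; member i is seeded with `seed + i`.
#' @param n_members Ensemble size (default 10; the consensus rule assumes
#'   10).
#' @return An object of class `determiner_ensemble` (list of
#'   `determiner_model`s).
#' @export
build_determiner_ensemble <- function(preset = "test_scale", seed = 1L,
                                      n_members = 10L) {
  archs <- rep(c("cnn", "lstm"), length.out = n_members)
  variants <- rep(1:5, each = 2L, length.out = n_members)
  members <- lapply(seq_len(n_members), function(i)
    build_determiner(determiner_config(archs[i], variants[i], preset,
                                       seed = seed + i)))
  structure(list(members = members), class = "determiner_ensemble")
}

#' @export
print.determiner_ensemble <- function(x, ...) {
  cat(sprintf("determiner_ensemble: %d members\n", length(x$members)))
  for (m in x$members) cat("  ", m$model_id, "\n")
  invisible(x)
}

#' Stream of synthetic label-indicator curve stacks
#'
#' Generates Determiner training inputs directly from labels, bypassing
#' Place-Back: for a random MSRL and rewrite window, the two curves of that
#' MSRL are the 0/1 indicator of the window and the other two curves are
#' zero. Used to verify that Determiner architectures can recover (MSRL,
#' OQPR) labels on a separable task.
#'
#' @param batch_size Stacks per batch.
#' @param seed Integer seed.
#' @param promoter_length Curve length (default 400).
#' @return A `stack_stream` whose `$next_batch()` returns a list of
#'   `list(stack, msrl, oqpr_bin)` records.
#' @export
indicator_stack_stream <- function(batch_size, seed, promoter_length = 400L) {
  env <- new.env(parent = emptyenv())
  old <- local_seed(seed)
  env$rng_state <- get(".Random.seed", envir = globalenv())
  restore_seed(old)
  next_batch <- function() {
    outer <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$rng_state, envir = globalenv())
    batch <- lapply(seq_len(batch_size), function(i) {
      msrl <- c(5L, 40L)[runif_int(1L, 2L)]
      st <- runif_int(0L, promoter_length - msrl)
      curves <- matrix(0, 4L, promoter_length)
      rows <- if (msrl == 5L) 1:2 else 3:4
      curves[rows, (st + 1L):(st + msrl)] <- 1
      list(stack = curve_stack(curves),
           msrl = msrl,
           oqpr_bin = oqpr_bin_of(c(st, st + msrl), promoter_length))
    })
    env$rng_state <- get(".Random.seed", envir = globalenv())
    restore_seed(outer)
    batch
  }
  structure(list(next_batch = next_batch, batch_size = batch_size),
            class = "stack_stream")
}

#' Stream of curve stacks produced by four Place-Back models
#'
#' Wraps a [sample_stream()] (typically configured with `msrl = c(5, 40)`)
#' so that each training sample is passed through the four Place-Back
#' models to build the Determiner's input stack, labelled with the sample's
#' true MSRL and OQPR bin.
#'
#' @param placebacks List of four `placeback_model`s with MSRL pattern
#'   (5, 5, 40, 40).
#' @param stream A [sample_stream()].
#' @return A `stack_stream`.
#' @export
placeback_stack_stream <- function(placebacks, stream) {
  check_placeback_pattern(placebacks)
  next_batch <- function() {
    lapply(stream$next_batch(), function(s) {
      curves <- lapply(placebacks, function(m)
        predict_placeback(m, s$disrupted_promoter, s$query))
      list(stack = curve_stack(curves, promoter_id = s$base_promoter_id,
                               query = s$query),
           msrl = s$msrl, oqpr_bin = s$oqpr_bin)
    })
  }
  structure(list(next_batch = next_batch, batch_size = stream$batch_size),
            class = "stack_stream")
}

check_placeback_pattern <- function(placebacks) {
  if (length(placebacks) != 4L ||
      !all(vapply(placebacks, inherits, logical(1), "placeback_model")))
    stop("placebacks must be a list of four placeback_model objects")
  msrls <- vapply(placebacks, function(m) m$config$msrl, integer(1))
  if (!identical(msrls, STACK_MSRL_ORDER))
    stop("placeback model bundle must have MSRL pattern (5, 5, 40, 40); got (",
         paste(msrls, collapse = ", "), ")")
  invisible(TRUE)
}

#' Train a Determiner model
#'
#' Minimizes the sum of the cross-entropies of the two heads against the
#' true (MSRL, OQPR bin) labels of each stack, with Adam.
#'
#' @param model A `determiner_model`.
#' @param stream A `stack_stream` ([indicator_stack_stream()] or
#'   [placeback_stack_stream()]), or a fixed list of
#'   `list(stack, msrl, oqpr_bin)` records trained as a full batch.
#' @param steps Optimizer steps.
#' @param lr Adam learning rate (default 3e-3).
#' @param verbose Print losses.
#' @return The model with a `trace` data frame in `model$trace`.
#' @export
train_determiner <- function(model, stream, steps, lr = 3e-3,
                             verbose = FALSE) {
  stopifnot(inherits(model, "determiner_model"))
  fixed <- is.list(stream) && !inherits(stream, "stack_stream")
  opt <- adam_new(model$params, lr = lr)
  trace <- list()
  for (step in seq_len(steps)) {
    batch <- if (fixed) stream else stream$next_batch()
    tp <- tape_new(grad_on = TRUE)
    losses <- lapply(batch, function(rec) {
      heads <- det_forward_one(model, tp, t(rec$stack$curves))
      lm <- t_ce_logits(tp, heads$msrl, match(rec$msrl, c(5L, 40L)))
      lr_ <- t_ce_logits(tp, heads$region, rec$oqpr_bin)
      t_add(tp, lm, lr_)
    })
    total <- t_scale(tp, Reduce(function(a, b) t_add(tp, a, b), losses),
                     1 / length(losses))
    loss <- as.numeric(tp_val(tp, total))
    if (!is.finite(loss))
      stop("non-finite loss at step ", step, "; lower the learning rate")
    backward(tp, total)
    adam_step(opt)
    if (verbose) message(sprintf("step %d loss %.4f", step, loss))
    trace[[step]] <- data.frame(step = step, loss = loss)
  }
  model$steps_trained <- model$steps_trained + steps
  model$trace <- do.call(rbind, trace)
  model
}

#' Label-recovery accuracy of a Determiner
#'
#' @param model A `determiner_model`.
#' @param records List of `list(stack, msrl, oqpr_bin)` records.
#' @return Named vector with `msrl_accuracy` and `region_accuracy`.
#' @export
determiner_accuracy <- function(model, records) {
  preds <- lapply(records, function(rec) predict_determiner(model, rec$stack))
  c(msrl_accuracy = mean(vapply(seq_along(records), function(i)
      preds[[i]]$msrl_pred == records[[i]]$msrl, logical(1))),
    region_accuracy = mean(vapply(seq_along(records), function(i)
      preds[[i]]$region_pred == records[[i]]$oqpr_bin, logical(1))))
}
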