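# Classifier construction with exact per-layer parameter accounting.
#
# Backbones are represented as layer-spec tables (name, shapes, parameter
# counts) built from generic counting rules -- dense: in*out + out; conv:
# out_ch * (kh*kw*in_ch) [+ out_ch if biased]; batch-norm: 4 per channel, of
# which the running mean/variance pair is counted as non-trainable (the
# convention under which DenseNet-121's 83,648 non-trainable parameters
# arise). The compact "tiny" backbone is additionally executable/trainable.

count_dense <- function(in_dim, out_dim) in_dim * out_dim + out_dim
count_conv <- function(k, in_ch, out_ch, bias = FALSE) {
  out_ch * (k * k * in_ch) + if (bias) out_ch else 0
}

spec_row <- function(name, type, in_shape, out_shape, trainable = 0,
                     non_trainable = 0) {
  tibble(name = name, type = type,
         input_shape = list(as.integer(in_shape)),
         output_shape = list(as.integer(out_shape)),
         params = trainable + non_trainable,
         trainable = trainable, non_trainable = non_trainable)
}

conv_spec <- function(name, in_shape, out_shape, k, bias = FALSE) {
  spec_row(name, "conv", in_shape, out_shape,
           trainable = count_conv(k, in_shape[3], out_shape[3], bias))
}
bn_spec <- function(name, shape) {
  ch <- shape[3]
  spec_row(name, "batchnorm", shape, shape, trainable = 2 * ch,
           non_trainable = 2 * ch) # gamma/beta train; running mean/var do not
}

densenet_layers <- function(blocks, growth = 32, input_shape = c(224, 224, 3)) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1]] <<- r
  hw <- input_shape[1:2]
  add(conv_spec("conv1", c(hw, input_shape[3]), c(hw %/% 2, 64), k = 7))
  hw <- hw %/% 2
  add(bn_spec("conv1_bn", c(hw, 64)))
  add(spec_row("pool1", "maxpool", c(hw, 64), c(hw %/% 2, 64)))
  hw <- hw %/% 2
  ch <- 64
  for (b in seq_along(blocks)) {
    for (l in seq_len(blocks[b])) {
      nm <- sprintf("block%d_layer%d", b, l)
      add(bn_spec(paste0(nm, "_bn1"), c(hw, ch)))
      add(conv_spec(paste0(nm, "_conv1x1"), c(hw, ch), c(hw, 4 * growth), k = 1))
      add(bn_spec(paste0(nm, "_bn2"), c(hw, 4 * growth)))
      add(conv_spec(paste0(nm, "_conv3x3"), c(hw, 4 * growth), c(hw, growth), k = 3))
      ch <- ch + growth
    }
    if (b < length(blocks)) { # 0.5-compression transition
      add(bn_spec(sprintf("transition%d_bn", b), c(hw, ch)))
      add(conv_spec(sprintf("transition%d_conv", b), c(hw, ch), c(hw, ch %/% 2), k = 1))
      add(spec_row(sprintf("transition%d_pool", b), "avgpool",
                   c(hw, ch %/% 2), c(hw %/% 2, ch %/% 2)))
      ch <- ch %/% 2
      hw <- hw %/% 2
    }
  }
  add(bn_spec("final_bn", c(hw, ch)))
  list(layers = bind_rows(rows), output_shape = c(hw, ch))
}

resnet50_layers <- function(input_shape = c(224, 224, 3)) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1]] <<- r
  hw <- input_shape[1:2] %/% 2
  add(conv_spec("conv1", input_shape, c(hw, 64), k = 7, bias = TRUE))
  add(bn_spec("conv1_bn", c(hw, 64)))
  add(spec_row("pool1", "maxpool", c(hw, 64), c(hw %/% 2, 64)))
  hw <- hw %/% 2
  ch <- 64
  widths <- c(64, 128, 256, 512)
  blocks <- c(3, 4, 6, 3)
  for (s in 1:4) {
    w <- widths[s]
    if (s > 1) hw <- hw %/% 2 # stride-2 first block
    for (l in seq_len(blocks[s])) {
      nm <- sprintf("stage%d_block%d", s, l)
      add(conv_spec(paste0(nm, "_conv1"), c(hw, ch), c(hw, w), k = 1, bias = TRUE))
      add(bn_spec(paste0(nm, "_bn1"), c(hw, w)))
      add(conv_spec(paste0(nm, "_conv2"), c(hw, w), c(hw, w), k = 3, bias = TRUE))
      add(bn_spec(paste0(nm, "_bn2"), c(hw, w)))
      add(conv_spec(paste0(nm, "_conv3"), c(hw, w), c(hw, 4 * w), k = 1, bias = TRUE))
      add(bn_spec(paste0(nm, "_bn3"), c(hw, 4 * w)))
      if (l == 1) {
        add(conv_spec(paste0(nm, "_shortcut"), c(hw, ch), c(hw, 4 * w), k = 1,
                      bias = TRUE))
        add(bn_spec(paste0(nm, "_shortcut_bn"), c(hw, 4 * w)))
      }
      ch <- 4 * w
    }
  }
  list(layers = bind_rows(rows), output_shape = c(hw, ch))
}

mobilenet_layers <- function(input_shape = c(224, 224, 3)) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1]] <<- r
  hw <- input_shape[1:2] %/% 2
  add(conv_spec("conv1", input_shape, c(hw, 32), k = 3))
  add(bn_spec("conv1_bn", c(hw, 32)))
  ch <- 32
  plan <- list(c(64, 1), c(128, 2), c(128, 1), c(256, 2), c(256, 1),
               c(512, 2), c(512, 1), c(512, 1), c(512, 1), c(512, 1),
               c(512, 1), c(1024, 2), c(1024, 1))
  for (i in seq_along(plan)) {
    out_ch <- plan[[i]][1]; stride <- plan[[i]][2]
    if (stride == 2) hw <- hw %/% 2
    nm <- sprintf("dw%d", i)
    # depthwise 3x3: 9 weights per input channel, no bias
    add(spec_row(paste0(nm, "_depthwise"), "conv", c(hw * stride, ch),
                 c(hw, ch), trainable = 9 * ch))
    add(bn_spec(paste0(nm, "_dw_bn"), c(hw, ch)))
    add(conv_spec(paste0(nm, "_pointwise"), c(hw, ch), c(hw, out_ch), k = 1))
    add(bn_spec(paste0(nm, "_pw_bn"), c(hw, out_ch)))
    ch <- out_ch
  }
  list(layers = bind_rows(rows), output_shape = c(hw, ch))
}

tiny_layers <- function(input_shape = c(224, 224, 3)) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1]] <<- r
  hw <- input_shape[1:2]
  # anisotropic pooling: joint-space narrowing and marginal osteophytes live
  # in the vertical profile, so rows are pooled more gently than columns
  pools <- list(c(2, 4), c(2, 2), c(4, 2))
  chans <- c(input_shape[3], 16, 32, 32)
  for (i in 1:3) {
    add(spec_row(sprintf("pool%d", i), "avgpool", c(hw, chans[i]),
                 c(hw %/% pools[[i]], chans[i])))
    hw <- hw %/% pools[[i]]
    if (i < 3) {
      add(conv_spec(sprintf("conv%d", i), c(hw, chans[i]), c(hw, chans[i + 1]),
                    k = 3, bias = TRUE))
      add(spec_row(sprintf("relu%d", i), "relu", c(hw, chans[i + 1]),
                   c(hw, chans[i + 1])))
    }
  }
  list(layers = bind_rows(rows), output_shape = c(hw, 32))
}

# executable layer list matching tiny_layers()
tiny_network_layers <- function(in_ch = 3) {
  list(nn_avgpool(c(2, 4)),
       nn_conv(in_ch, 16), nn_relu(), nn_avgpool(c(2, 2)),
       nn_conv(16, 32), nn_relu(), nn_avgpool(c(4, 2)))
}

backbone_registry <- function() {
  c("densenet121", "densenet201", "resnet50", "mobilenet", "tiny")
}

#' Build a feature-extractor backbone
#'
#' Returns the backbone's per-layer specification (shapes and trainable /
#' non-trainable parameter counts from generic counting rules) and its output
#' feature-map shape for the given input. `"densenet121"` is the canonical
#' architecture: 7x7/2 stem of 64 channels, dense blocks of 6/12/24/16
#' layers with growth rate 32 and 1x1 bottlenecks, 0.5-compression
#' transitions, batch normalization throughout, emitting 7 x 7 x 1024
#' features for 224 x 224 x 3 input. The `"tiny"` backbone is a compact
#' conv / average-pool stack that is executable and trainable on a CPU.
#'
#' @param name One of `"densenet121"`, `"densenet201"`, `"resnet50"`,
#'   `"mobilenet"`, `"tiny"`.
#' @param input_shape `(height, width, channels)` of the backbone input.
#' @param pretrained Load pretrained weights. No weight bundle ships with the
#'   package, so this requires `weights`; all tests run with random
#'   initialization.
#' @param weights Optional path to an RDS file of weight arrays (only
#'   supported for the executable `"tiny"` backbone).
#' @return A list of class `"kg_backbone"` with elements `name`, `layers`
#'   (spec tibble), `output_shape`, `total`, `trainable`, `non_trainable`.
#' @export
#' @examples
#' b <- build_backbone("densenet121")
#' b$output_shape
build_backbone <- function(name, input_shape = c(224, 224, 3),
                           pretrained = FALSE, weights = NULL) {
  if (!name %in% backbone_registry()) {
    abort(sprintf("Unknown backbone \"%s\". Registry: %s.", name,
                  paste(backbone_registry(), collapse = ", ")))
  }
  spec <- switch(name,
    densenet121 = densenet_layers(c(6, 12, 24, 16), input_shape = input_shape),
    densenet201 = densenet_layers(c(6, 12, 48, 32), input_shape = input_shape),
    resnet50 = resnet50_layers(input_shape),
    mobilenet = mobilenet_layers(input_shape),
    tiny = tiny_layers(input_shape)
  )
  if (isTRUE(pretrained) && is.null(weights)) {
    abort(paste("No pretrained weight bundle ships with this package;",
                "supply `weights` or use pretrained = FALSE (random init)."))
  }
  structure(list(
    name = name,
    layers = spec$layers,
    input_shape = as.integer(input_shape),
    output_shape = as.integer(spec$output_shape),
    total = sum(spec$layers$params),
    trainable = sum(spec$layers$trainable),
    non_trainable = sum(spec$layers$non_trainable),
    weights = weights
  ), class = "kg_backbone")
}

#' Classification-head configuration
#'
#' Fully connected head 128 / 64 / 16 -> n_classes with ReLU activations,
#' L2 weight regularization and dropout after each hidden activation, and a
#' softmax output.
#'
#' @param fc_widths Hidden layer widths, strictly decreasing.
#' @param n_classes Number of output classes.
#' @param l2_lambda L2 penalty weight on the fully connected kernels.
#' @param dropout_rate Dropout rate after each hidden activation, in `[0, 1)`.
#' @return A list of class `"head_config"`.
#' @export
head_config <- function(fc_widths = c(128, 64, 16), n_classes = 5,
                        l2_lambda = 1e-4, dropout_rate = 0.3) {
  if (any(fc_widths <= 0) || any(diff(fc_widths) >= 0)) {
    abort("fc_widths must be positive and strictly decreasing.")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1).")
  stopifnot(n_classes >= 2, l2_lambda >= 0)
  structure(list(fc_widths = as.integer(fc_widths),
                 n_classes = as.integer(n_classes),
                 l2_lambda = l2_lambda, dropout_rate = dropout_rate),
            class = "head_config")
}

#' Build the KL-grading classifier
#'
#' Assembles the full model: a 3x3 same-padding convolution adapting the
#' single-channel radiograph to the 3-channel backbone input (with ReLU),
#' the backbone, a flatten, and the fully connected head with softmax
#' output -- together with a per-layer summary whose parameter counts come
#' from generic counting rules. With `backbone = "tiny"` the returned model
#' is executable and trainable; the large ImageNet backbones are represented
#' by their exact layer accounting.
#'
#' @param head A [head_config()].
#' @param backbone Backbone name (see [build_backbone()]) or a
#'   `"kg_backbone"` object.
#' @param input_shape `(height, width)` of the single-channel input slice.
#' @param seed Seed for weight initialization of the executable profile.
#' @return A list of class `"kg_model"`: `summary` (condensed per-layer
#'   tibble), `detail` (fully expanded layer accounting), `total`,
#'   `trainable`, `non_trainable`, `head`, `backbone`, and `network` (the
#'   executable net, or `NULL` for accounting-only backbones).
#' @export
#' @examples
#' m <- build_model(backbone = "densenet121")
#' m$total
build_model <- function(head = head_config(), backbone = "densenet121",
                        input_shape = c(224, 224), seed = NULL) {
  stopifnot(inherits(head, "head_config"))
  if (is.character(backbone)) backbone <- build_backbone(backbone)
  stopifnot(inherits(backbone, "kg_backbone"))
  hw <- as.integer(input_shape[1:2])

  adapter <- conv_spec("conv2d_adapter", c(hw, 1L), c(hw, 3L), k = 3, bias = TRUE)
  flat_dim <- prod(backbone$output_shape)

  rows <- list(
    spec_row("input", "input", c(hw, 1L), c(hw, 1L)),
    adapter,
    spec_row("activation_relu_0", "relu", c(hw, 3L), c(hw, 3L)),
    spec_row(paste0(backbone$name, "_basenet"), "backbone",
             c(hw, 3L), backbone$output_shape,
             trainable = backbone$trainable,
             non_trainable = backbone$non_trainable),
    spec_row("flatten", "flatten", backbone$output_shape, flat_dim)
  )
  in_dim <- flat_dim
  for (i in seq_along(head$fc_widths)) {
    w <- head$fc_widths[i]
    rows[[length(rows) + 1]] <- spec_row(sprintf("fc_%d", i), "dense", in_dim, w,
                                         trainable = count_dense(in_dim, w))
    rows[[length(rows) + 1]] <- spec_row(sprintf("activation_relu_%d", i), "relu", w, w)
    in_dim <- w
  }
  rows[[length(rows) + 1]] <- spec_row(sprintf("fc_%d", length(head$fc_widths) + 1),
                                       "dense", in_dim, head$n_classes,
                                       trainable = count_dense(in_dim, head$n_classes))
  rows[[length(rows) + 1]] <- spec_row("activation_softmax", "softmax",
                                       head$n_classes, head$n_classes)
  summary_tbl <- bind_rows(rows)

  detail <- bind_rows(
    summary_tbl[summary_tbl$type != "backbone", ],
    backbone$layers
  )

  network <- NULL
  if (backbone$name == "tiny") {
    layers <- c(
      list(nn_conv(1, 3, k = 3, padding = "same"), nn_relu()),
      tiny_network_layers(3),
      list(nn_flatten())
    )
    in_dim <- flat_dim
    for (w in head$fc_widths) {
      layers <- c(layers, list(nn_dense(in_dim, w, l2 = head$l2_lambda),
                               nn_relu(), nn_dropout(head$dropout_rate)))
      in_dim <- w
    }
    layers <- c(layers, list(nn_dense(in_dim, head$n_classes, l2 = head$l2_lambda)))
    network <- init_network(layers, seed = seed)
    if (!is.null(backbone$weights)) {
      loaded <- readRDS(backbone$weights)
      network <- net_set_params(network, loaded)
    }
  }

  structure(list(
    summary = summary_tbl,
    detail = detail,
    total = sum(summary_tbl$params),
    trainable = sum(summary_tbl$trainable),
    non_trainable = sum(summary_tbl$non_trainable),
    head = head,
    backbone = backbone,
    input_shape = hw,
    network = network
  ), class = "kg_model")
}

#' Per-layer model summary
#'
#' @param model A `"kg_model"` from [build_model()].
#' @param detail Return the fully expanded backbone accounting instead of the
#'   condensed table.
#' @return A tibble with layer name, type, input/output shapes and parameter
#'   counts; total counts are attached as attributes `total`, `trainable`,
#'   `non_trainable`.
#' @export
model_summary <- function(model, detail = FALSE) {
  stopifnot(inherits(model, "kg_model"))
  out <- if (detail) model$detail else model$summary
  attr(out, "total") <- model$total
  attr(out, "trainable") <- model$trainable
  attr(out, "non_trainable") <- model$non_trainable
  out
}

#' @export
tidy.kg_model <- function(x, detail = FALSE, ...) {
  tbl <- model_summary(x, detail = detail)
  tbl$input_shape <- vapply(tbl$input_shape, paste, "", collapse = "x")
  tbl$output_shape <- vapply(tbl$output_shape, paste, "", collapse = "x")
  tbl
}

#' @export
glance.kg_model <- function(x, ...) {
  tibble(backbone = x$backbone$name,
         total_params = x$total,
         trainable_params = x$trainable,
         non_trainable_params = x$non_trainable,
         executable = !is.null(x$network))
}

#' @export
print.kg_model <- function(x, ...) {
  cat(sprintf("<kg_model> backbone = %s%s\n", x$backbone$name,
              if (is.null(x$network)) " (accounting only)" else " (trainable)"))
  tbl <- tidy(x)
  fmt <- format(tbl$params, big.mark = ",")
  for (i in seq_len(nrow(tbl))) {
    cat(sprintf("  %-22s %-14s -> %-14s %12s\n", tbl$name[i],
                tbl$input_shape[i], tbl$output_shape[i], fmt[i]))
  }
  cat(sprintf("  Total parameters         %s\n", format(x$total, big.mark = ",")))
  cat(sprintf("  Trainable parameters     %s\n", format(x$trainable, big.mark = ",")))
  cat(sprintf("  Non-trainable parameters %s\n", format(x$non_trainable, big.mark = ",")))
  invisible(x)
}
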