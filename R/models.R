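#' Model specification
#'
#' Validated description of one risk network.  Supported kinds and
#' hyperparameter grids: `mlp` (two hidden layers of width 32, 64 or
#' 128, GELU activations), `resnet2d` (18, 34 or 50 layers, coronal MIP
#' input), `resnet3d` (10, 18 or 34 layers, volume input), and
#' `multimodal` (a `resnet3d` spec plus an `mlp` spec fused by
#' concatenating their penultimate representations under a single linear
#' risk head).
#'
#' @param kind one of `"mlp"`, `"resnet2d"`, `"resnet3d"`,
#'   `"multimodal"`.
#' @param hidden_width MLP hidden width (32, 64 or 128).
#' @param layers residual-network depth (2D: 18/34/50; 3D: 10/18/34).
#' @param in_channels input channels for image networks.
#' @param resnet3d,mlp sub-specs for the multimodal model; defaults are
#'   the best-performing unimodal configurations (ResNet3D-34, MLP-64).
#' @return Object of class `model_spec` (a named list, serializable to
#'   YAML/JSON).
#' @export
model_spec <- function(kind = c("mlp", "resnet2d", "resnet3d", "multimodal"),
                       hidden_width = 64, layers = NULL, in_channels = 1,
                       resnet3d = NULL, mlp = NULL) {
  kind <- match.arg(kind)
  spec <- list(kind = kind)
  if (kind == "mlp") {
    if (!hidden_width %in% c(32, 64, 128)) {
      stop("unsupported MLP width: ", hidden_width,
           " (supported: 32, 64, 128)")
    }
    spec$hidden_width <- hidden_width
  } else if (kind == "resnet2d") {
    layers <- if (is.null(layers)) 18 else layers
    if (!layers %in% c(18, 34, 50)) {
      stop("unsupported ResNet2D depth: ", layers,
           " (supported: 18, 34, 50)")
    }
    spec$layers <- layers
    spec$in_channels <- in_channels
  } else if (kind == "resnet3d") {
    layers <- if (is.null(layers)) 34 else layers
    if (!layers %in% c(10, 18, 34)) {
      stop("unsupported ResNet3D depth: ", layers,
           " (supported: 10, 18, 34)")
    }
    spec$layers <- layers
    spec$in_channels <- in_channels
  } else {
    spec$resnet3d <- if (is.null(resnet3d)) {
      model_spec("resnet3d", layers = 34, in_channels = in_channels)
    } else do.call(model_spec, c(list(kind = "resnet3d"), resnet3d))
    spec$mlp <- if (is.null(mlp)) model_spec("mlp", hidden_width = 64) else
      do.call(model_spec, c(list(kind = "mlp"), mlp))
  }
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$kind,
      if (!is.null(x$hidden_width)) paste0("width=", x$hidden_width),
      if (!is.null(x$layers)) paste0("layers=", x$layers), "\n")
  invisible(x)
}

resnet_plan <- function(layers, nd) {
  if (nd == 3) {
    counts <- switch(as.character(layers),
                     "10" = c(1, 1, 1, 1), "18" = c(2, 2, 2, 2),
                     "34" = c(3, 4, 6, 3))
    list(counts = counts, bottleneck = FALSE, conv1_k = 3, conv1_p = 1)
  } else {
    counts <- switch(as.character(layers),
                     "18" = c(2, 2, 2, 2), "34" = c(3, 4, 6, 3),
                     "50" = c(3, 4, 6, 3))
    list(counts = counts, bottleneck = layers == 50, conv1_k = 7,
         conv1_p = 3)
  }
}

build_resnet_trunk <- function(layers, nd, in_channels, f64) {
  plan <- resnet_plan(layers, nd)
  widths <- c(64, 128, 256, 512)
  stem <- layer_conv(in_channels, 64, nd, plan$conv1_k, 2, plan$conv1_p,
                     f64)
  stem$need_dx <- FALSE  # nothing trainable below the stem
  trunk <- list(stem, layer_batchnorm(64), layer_relu(), layer_maxpool())
  c_in <- 64
  for (s in 1:4) {
    stride <- if (s == 1) 1 else 2
    for (b in seq_len(plan$counts[s])) {
      blk <- if (plan$bottleneck) {
        block_bottleneck(c_in, widths[s], nd, if (b == 1) stride else 1, f64)
      } else {
        block_basic(c_in, widths[s], nd, if (b == 1) stride else 1, f64)
      }
      trunk <- c(trunk, list(blk))
      c_in <- if (plan$bottleneck) 4 * widths[s] else widths[s]
    }
  }
  trunk <- c(trunk, list(layer_gap()))
  list(trunk = trunk, feature_dim = c_in)
}

build_mlp_trunk <- function(input_dim, hidden_width) {
  list(layer_linear(input_dim, hidden_width), layer_gelu(),
       layer_linear(hidden_width, hidden_width), layer_gelu())
}

new_model <- function(kind, spec) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$spec <- spec
  class(m) <- "petsurv_model"
  m
}

#' Build a DeepSurv-style MLP risk network
#'
#' Input covariates pass through two hidden layers of the given width
#' with GELU activations into a single linear risk output (the log
#' relative hazard).
#'
#' @param input_dim number of design-matrix columns.
#' @param hidden_width hidden-layer width (32, 64 or 128).
#' @param seed integer seed for the weight initialization.
#' @param f64 use the double-precision kernel path (slower; for
#'   gradient checks).
#' @return Object of class `petsurv_model`.
#' @export
build_mlp <- function(input_dim, hidden_width = 64, seed = 1, f64 = FALSE) {
  spec <- model_spec("mlp", hidden_width = hidden_width)
  stopifnot(input_dim >= 1)
  m <- new_model("mlp", spec)
  with_seed(seed, {
    m$trunk <- build_mlp_trunk(input_dim, hidden_width)
    m$head <- layer_linear(hidden_width, 1)
  })
  m$input_dim <- input_dim
  m$feature_dim <- hidden_width
  m$f64 <- f64
  m
}

#' Build a 2D residual network for coronal MIP images
#'
#' Standard residual topology (basic blocks at depth 18/34, bottleneck
#' blocks at depth 50) on single-channel projections: a 7x7 stride-2
#' stem, 2x max pooling, four stages of residual blocks with stride-2
#' downsampling, global average pooling, and a single-scalar linear risk
#' head.
#'
#' @param layers depth: 18, 34 or 50.
#' @param in_channels input channels (1 for MIP).
#' @inheritParams build_mlp
#' @return Object of class `petsurv_model`.
#' @export
build_resnet2d <- function(layers = 18, in_channels = 1, seed = 1,
                           f64 = FALSE) {
  spec <- model_spec("resnet2d", layers = layers, in_channels = in_channels)
  m <- new_model("resnet2d", spec)
  with_seed(seed, {
    tr <- build_resnet_trunk(layers, 2, in_channels, f64)
    m$trunk <- tr$trunk
    m$head <- layer_linear(tr$feature_dim, 1)
    m$feature_dim <- tr$feature_dim
  })
  m$f64 <- f64
  m
}

#' Build a 3D residual network for PET volumes
#'
#' Residual 3D topology with 3x3x3 kernels throughout: a stride-2 stem
#' convolution, 2x max pooling, four stages of basic blocks (widths
#' 64-128-256-512) with stride-2 convolutions for downsampling, batch
#' normalization and ReLU after each convolution, adaptive (global)
#' average pooling to a 512-long feature vector, and a single-scalar
#' linear risk head.  The pooled feature vector is what the multimodal
#' model fuses.
#'
#' @param layers depth: 10, 18 or 34.
#' @inheritParams build_resnet2d
#' @return Object of class `petsurv_model`.
#' @export
build_resnet3d <- function(layers = 34, in_channels = 1, seed = 1,
                           f64 = FALSE) {
  spec <- model_spec("resnet3d", layers = layers, in_channels = in_channels)
  m <- new_model("resnet3d", spec)
  with_seed(seed, {
    tr <- build_resnet_trunk(layers, 3, in_channels, f64)
    m$trunk <- tr$trunk
    m$head <- layer_linear(tr$feature_dim, 1)
    m$feature_dim <- tr$feature_dim
  })
  m$f64 <- f64
  m
}

#' Build the joint-fusion multimodal risk network
#'
#' Concatenates the ResNet3D pooled feature vector (512) with the MLP's
#' last hidden activation and applies a single linear risk head; the
#' whole graph is trainable end-to-end (joint fusion).  Defaults follow
#' the best unimodal configurations: ResNet3D-34 and MLP-64.
#'
#' @param input_dim clinical design-matrix width.
#' @param resnet3d_spec list of arguments for the image branch
#'   (`layers`, `in_channels`).
#' @param mlp_spec list of arguments for the clinical branch
#'   (`hidden_width`).
#' @param image_model,clinical_model optional trained unimodal
#'   `petsurv_model`s whose trunk weights warm-start the corresponding
#'   branch (default: train from scratch).
#' @inheritParams build_mlp
#' @return Object of class `petsurv_model` with `kind = "multimodal"`.
#' @export
build_multimodal <- function(input_dim,
                             resnet3d_spec = list(layers = 34),
                             mlp_spec = list(hidden_width = 64),
                             image_model = NULL, clinical_model = NULL,
                             seed = 1, f64 = FALSE) {
  spec <- model_spec("multimodal", resnet3d = resnet3d_spec, mlp = mlp_spec)
  m <- new_model("multimodal", spec)
  with_seed(seed, {
    tr <- build_resnet_trunk(spec$resnet3d$layers, 3,
                             spec$resnet3d$in_channels, f64)
    m$image_trunk <- tr$trunk
    m$image_feature_dim <- tr$feature_dim
    m$clin_trunk <- build_mlp_trunk(input_dim, spec$mlp$hidden_width)
    m$clin_feature_dim <- spec$mlp$hidden_width
    m$head <- layer_linear(tr$feature_dim + spec$mlp$hidden_width, 1)
  })
  m$input_dim <- input_dim
  m$feature_dim <- m$image_feature_dim + m$clin_feature_dim
  m$f64 <- f64
  if (!is.null(image_model)) {
    stopifnot(image_model$kind == "resnet3d")
    copy_trunk_weights(image_model$trunk, m$image_trunk)
  }
  if (!is.null(clinical_model)) {
    stopifnot(clinical_model$kind == "mlp")
    copy_trunk_weights(clinical_model$trunk, m$clin_trunk)
  }
  m
}

copy_trunk_weights <- function(from, to) {
  a <- collect_layers(from)
  b <- collect_layers(to)
  stopifnot(length(a) == length(b))
  for (i in seq_along(a)) {
    stopifnot(identical(lapply(a[[i]]$params, dim),
                        lapply(b[[i]]$params, dim)))
    b[[i]]$params <- lapply(a[[i]]$params, function(p) p + 0)
    if (a[[i]]$type == "batchnorm") {
      b[[i]]$running_mean <- a[[i]]$running_mean + 0
      b[[i]]$running_var <- a[[i]]$running_var + 0
    }
  }
  invisible(to)
}

#' @export
print.petsurv_model <- function(x, ...) {
  cat(sprintf("<petsurv_model> %s, %s parameters\n", x$kind,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

model_layer_list <- function(model) {
  if (model$kind == "multimodal") {
    c(collect_layers(model$image_trunk), collect_layers(model$clin_trunk),
      collect_layers(list(model$head)))
  } else {
    c(collect_layers(model$trunk), collect_layers(list(model$head)))
  }
}

#' Number of trainable parameters
#'
#' @param model a `petsurv_model`.
#' @return Integer parameter count over all weights and biases.
#' @export
count_parameters <- function(model) {
  sum(vapply(model_layer_list(model),
             function(ly) sum(vapply(ly$params, length, 1L)), 1))
}

# Assemble a batch activation from a model-inputs object and row indices.
volume_act <- function(mat, dims, idx) {
  new_act(matrix(as.vector(t(mat[idx, , drop = FALSE])), ncol = 1),
          dims, length(idx))
}

#' Bundle model inputs
#'
#' Groups the per-subject network inputs: the clinical design matrix,
#' flattened PET volumes (one row per subject, positions column-major)
#' with their spatial dims, and/or flattened coronal MIPs.
#'
#' @param design numeric design matrix (subjects x covariate columns).
#' @param volumes matrix of flattened volumes (subjects x voxels).
#' @param vol_dims integer length-3 spatial dims of each volume.
#' @param mips matrix of flattened MIP images (subjects x pixels).
#' @param mip_dims integer length-2 spatial dims of each MIP.
#' @return Object of class `model_inputs`.
#' @export
model_inputs <- function(design = NULL, volumes = NULL, vol_dims = NULL,
                         mips = NULL, mip_dims = NULL) {
  if (!is.null(volumes)) stopifnot(length(vol_dims) == 3,
                                   ncol(volumes) == prod(vol_dims))
  if (!is.null(mips)) stopifnot(length(mip_dims) == 2,
                                ncol(mips) == prod(mip_dims))
  out <- list(design = design, volumes = volumes,
              vol_dims = as.integer(vol_dims),
              mips = mips, mip_dims = as.integer(mip_dims))
  class(out) <- "model_inputs"
  out
}

#' Number of subjects in a model-inputs bundle
#' @param inputs a [model_inputs()] object.
#' @return Integer subject count.
#' @export
n_inputs <- function(inputs) {
  for (f in c("design", "volumes", "mips")) {
    if (!is.null(inputs[[f]])) return(nrow(inputs[[f]]))
  }
  stop("empty model_inputs")
}

#' Subset a model-inputs bundle by subject indices
#' @param inputs a [model_inputs()] object.
#' @param idx integer indices.
#' @return A `model_inputs` restricted to `idx`.
#' @export
subset_inputs <- function(inputs, idx) {
  out <- inputs
  for (f in c("design", "volumes", "mips")) {
    if (!is.null(out[[f]])) out[[f]] <- out[[f]][idx, , drop = FALSE]
  }
  out
}

require_modality <- function(inputs, field, kind) {
  if (is.null(inputs[[field]])) {
    stop(sprintf("model kind '%s' requires the '%s' modality in its inputs",
                 kind, field))
  }
}

# Standardization of the clinical design, fitted on training data only
# (stored on the model, applied at every forward pass).
fit_design_scaler <- function(design) {
  ctr <- colMeans(design)
  scl <- apply(design, 2, sd)
  scl[scl < 1e-8] <- 1
  list(center = ctr, scale = scl)
}

apply_design_scaler <- function(scaler, design) {
  if (is.null(scaler)) return(design)
  sweep(sweep(design, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# Forward pass over a batch.  Returns the risk vector; with
# training = TRUE, caches are retained for model_backward().
model_forward <- function(model, inputs, idx = NULL, training = FALSE) {
  if (is.null(idx)) idx <- seq_len(n_inputs(inputs))
  if (model$kind == "mlp") {
    require_modality(inputs, "design", model$kind)
    act <- new_act(apply_design_scaler(model$scaler,
                                       inputs$design[idx, , drop = FALSE]),
                   integer(0), length(idx))
    feat <- seq_fw(model$trunk, act, training)
  } else if (model$kind == "resnet3d") {
    require_modality(inputs, "volumes", model$kind)
    act <- volume_act(inputs$volumes, inputs$vol_dims, idx)
    feat <- seq_fw(model$trunk, act, training)
  } else if (model$kind == "resnet2d") {
    require_modality(inputs, "mips", model$kind)
    act <- volume_act(inputs$mips, inputs$mip_dims, idx)
    feat <- seq_fw(model$trunk, act, training)
  } else {
    require_modality(inputs, "volumes", model$kind)
    require_modality(inputs, "design", model$kind)
    img <- seq_fw(model$image_trunk,
                  volume_act(inputs$volumes, inputs$vol_dims, idx), training)
    cln <- seq_fw(model$clin_trunk,
                  new_act(apply_design_scaler(
                    model$scaler, inputs$design[idx, , drop = FALSE]),
                    integer(0), length(idx)), training)
    feat <- new_act(cbind(img$x, cln$x), integer(0), length(idx))
  }
  out <- model$head$fw(feat, training)
  risks <- as.vector(out$x)
  if (any(!is.finite(risks))) stop("non-finite risk scores in forward pass")
  risks
}

# Backpropagate d(loss)/d(risk) through the cached forward pass.
model_backward <- function(model, drisk) {
  dact <- model$head$bw(new_act(matrix(drisk, ncol = 1), integer(0),
                                length(drisk)))
  if (model$kind == "multimodal") {
    p <- model$image_feature_dim
    d_img <- new_act(dact$x[, seq_len(p), drop = FALSE], integer(0), dact$n)
    d_cln <- new_act(dact$x[, -seq_len(p), drop = FALSE], integer(0), dact$n)
    seq_bw(model$image_trunk, d_img)
    seq_bw(model$clin_trunk, d_cln)
  } else {
    seq_bw(model$trunk, dact)
  }
  invisible(NULL)
}

#' Predict log relative hazards
#'
#' Inference-mode forward pass (batch-norm running statistics, no
#' caches), chunked to bound memory on volume inputs.
#'
#' @param model a `petsurv_model`.
#' @param inputs a [model_inputs()] object.
#' @param chunk_size subjects per forward chunk.
#' @return Numeric vector of log relative hazards, one per subject.
#' @export
predict_risk <- function(model, inputs, chunk_size = 16) {
  n <- n_inputs(inputs)
  out <- numeric(n)
  for (start in seq(1, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1, n)
    out[idx] <- model_forward(model, inputs, idx, training = FALSE)
  }
  out
}

# Snapshot / restore all trainable state (weights + batch-norm running
# statistics); used by early stopping and checkpointing.
model_state <- function(model) {
  lapply(model_layer_list(model), function(ly) {
    st <- lapply(ly$params, function(p) p + 0)
    if (ly$type == "batchnorm") {
      st$running_mean <- ly$running_mean + 0
      st$running_var <- ly$running_var + 0
    }
    st
  })
}

set_model_state <- function(model, state) {
  layers <- model_layer_list(model)
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    st <- state[[i]]
    for (nm in names(ly$params)) ly$params[[nm]] <- st[[nm]] + 0
    if (ly$type == "batchnorm") {
      ly$running_mean <- st$running_mean + 0
      ly$running_var <- st$running_var + 0
    }
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' Serializes the model spec, input contract and all trainable state.
#'
#' @param model a `petsurv_model`.
#' @param path checkpoint file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a rebuilt `petsurv_model`.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(spec = unclass(model$spec),
                  input_dim = model$input_dim,
                  f64 = model$f64,
                  scaler = model$scaler,
                  state = model_state(model))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  spec <- payload$spec
  model <- switch(spec$kind,
    mlp = build_mlp(payload$input_dim, spec$hidden_width,
                    f64 = payload$f64),
    resnet2d = build_resnet2d(spec$layers, spec$in_channels,
                              f64 = payload$f64),
    resnet3d = build_resnet3d(spec$layers, spec$in_channels,
                              f64 = payload$f64),
    multimodal = build_multimodal(
      payload$input_dim,
      resnet3d_spec = spec$resnet3d[setdiff(names(spec$resnet3d), "kind")],
      mlp_spec = spec$mlp[setdiff(names(spec$mlp), "kind")],
      f64 = payload$f64))
  set_model_state(model, payload$state)
  model$scaler <- payload$scaler
  model
}
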