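#' Save a trained model to a single JSON checkpoint
#'
#' The checkpoint stores the configuration, every named weight array
#' (with dimensions) and the batch-norm running statistics; it is
#' plain text and loads back to a model that predicts identically.
#'
#' @param m a `hybrid_model`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_model <- function(m, path) {
  enc <- function(x) list(dim = if (is.null(dim(x))) length(x) else dim(x),
                          data = as.numeric(x))
  obj <- list(
    config = unclass(m$cfg),
    params = lapply(m$params, enc),
    state = lapply(m$state, function(s) list(mean = s$mean, var = s$var))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint written by [save_model()].
#' @param graph optional `joint_graph`; rebuilt from the default joint
#'   set when the skeleton branch is active and none is given.
#' @return a `hybrid_model` ready for [predict_hybrid()].
#' @export
load_model <- function(path, graph = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- hybrid_config(
    n_classes = cfg$n_classes,
    skeleton_channels = cfg$skeleton_channels,
    skeleton_strides = cfg$skeleton_strides,
    temporal_kernel = cfg$temporal_kernel,
    skeleton_out = cfg$skeleton_out, residual = cfg$residual,
    lstm_layers = cfg$lstm_layers, lstm_hidden = cfg$lstm_hidden,
    angle_dim = cfg$angle_dim, angle_out = cfg$angle_out,
    angle_scale = cfg$angle_scale,
    param_dim = cfg$param_dim, param_out = cfg$param_out,
    dropout = cfg$dropout, lambda = cfg$lambda,
    branches = cfg$branches, seed = cfg$seed
  )
  m <- hybrid_model(config, graph)
  for (nm in names(obj$params)) {
    p <- obj$params[[nm]]
    x <- as.numeric(p$data)
    if (length(p$dim) > 1) dim(x) <- p$dim
    m$params[[nm]] <- x
  }
  for (nm in names(obj$state)) {
    m$state[[nm]] <- list(mean = as.numeric(obj$state[[nm]]$mean),
                          var = as.numeric(obj$state[[nm]]$var))
  }
  m
}
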