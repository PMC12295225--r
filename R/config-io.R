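# Configuration files and checkpoints. Model configurations round-trip
# through YAML (keys mirror model_config()); checkpoints store the
# configuration together with a named parameter list so a model can be
# rebuilt bit-identically.

#' Write a model configuration to YAML
#'
#' @param cfg A [model_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_model_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$flags <- NULL
  x$dic <- unclass(x$dic)
  x$dic$branch_channels <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' @param path YAML file with keys mirroring [model_config()] arguments.
#' @return A `model_config`.
#' @export
load_model_config <- function(path) {
  x <- yaml::read_yaml(path)
  dic <- NULL
  if (!is.null(x$dic)) dic <- do.call(dic_config, x$dic)
  x$dic <- NULL
  x <- x[names(x) %in% names(formals(model_config))]
  do.call(model_config, c(x, list(dic = dic)))
}

#' Extract all model parameters as a named list
#'
#' @param model A model or layer.
#' @return Named list of parameter arrays.
#' @export
get_parameters <- function(model) {
  refs <- nn_collect(model)
  lapply(refs, function(r) r$env[[r$field]])
}

#' Overwrite model parameters from a named list
#'
#' @param model A model or layer (modified in place).
#' @param params Named list as produced by [get_parameters()].
#' @return `model`, invisibly.
#' @export
set_parameters <- function(model, params) {
  refs <- nn_collect(model)
  for (nm in names(params)) {
    r <- refs[[nm]]
    if (is.null(r)) stop("unknown parameter '", nm, "'")
    if (length(r$env[[r$field]]) != length(params[[nm]]))
      stop("shape mismatch for parameter '", nm, "'")
    dim0 <- dim(r$env[[r$field]])
    p <- params[[nm]]
    if (!is.null(dim0)) dim(p) <- dim0
    r$env[[r$field]] <- p
  }
  invisible(model)
}

#' Save a model checkpoint (configuration + parameters)
#'
#' @param model A model from [build_model()].
#' @param path Output file (RDS).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  qact <- if (!is.null(model$qact)) list(lo = model$qact$lo, hi = model$qact$hi,
                                         bit_width = model$qact$bit_width)
  saveRDS(list(cfg = model$cfg, params = get_parameters(model), qact = qact),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @return A rebuilt model with the stored parameters.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- build_model(ck$cfg, seed = 0L)
  set_parameters(m, ck$params)
  if (!is.null(ck$qact) && !is.null(m$qact)) {
    m$qact$lo <- ck$qact$lo
    m$qact$hi <- ck$qact$hi
  }
  m
}

#' Path of the packaged default profile
#'
#' The shipped `ilvit-default` profile holds the calibrated geometry of the
#' default model family (see the profile file for derivation notes).
#'
#' @return File path inside the installed package.
#' @export
default_profile_path <- function() {
  system.file("profiles", "ilvit-default.yaml", package = "ilvit")
}
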