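#' @useDynLib stripfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Minimal layer framework.
#
# A module is an environment carrying either
#   * leaf layer:  $par (named list of arrays), $grad (same shapes),
#                  optionally $buffers (non-trainable state, e.g. batch-norm
#                  running statistics), plus $forward(x, training) and
#                  $backward(dy) closures that cache what they need between
#                  the two calls, or
#   * composite:   $children (named list of sub-modules) plus its own
#                  forward/backward closures that chain the children.
#
# Gradients accumulate into $grad until nn_zero_grad() clears them, mirroring
# the usual deep-learning framework contract.
# ---------------------------------------------------------------------------

new_module <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- list()
  e$grad <- list()
  e$buffers <- list()
  e$children <- list()
  class(e) <- c(paste0("sf_", type), "sf_module")
  e
}

#' Run a module forward
#'
#' @param module a network or layer built by this package
#' @param x input (shape depends on the module)
#' @param training logical; `TRUE` enables batch-statistics batch norm and
#'   dropout, `FALSE` gives the deterministic evaluation path
#' @return the module output
#' @export
nn_forward <- function(module, x, training = FALSE) {
  stopifnot(inherits(module, "sf_module"))
  module$forward(x, training)
}

#' Back-propagate through a module
#'
#' Must follow a `nn_forward(..., training = TRUE)` call on the same module;
#' accumulates parameter gradients in place and returns the gradient with
#' respect to the module input.
#'
#' @param module a network or layer
#' @param dy gradient of the loss with respect to the module output
#' @return gradient with respect to the module input
#' @export
nn_backward <- function(module, dy) {
  stopifnot(inherits(module, "sf_module"))
  module$backward(dy)
}

# Depth-first walk over all modules; calls fn(module, path) on every node.
nn_walk <- function(module, fn, path = "") {
  fn(module, path)
  kids <- module$children
  for (nm in names(kids)) {
    nn_walk(kids[[nm]], fn, if (nzchar(path)) paste(path, nm, sep = "/") else nm)
  }
  invisible(NULL)
}

# List of list(env=, name=, path=) for every trainable tensor.
nn_parameters <- function(module) {
  out <- list()
  nn_walk(module, function(m, path) {
    for (nm in names(m$par)) {
      out[[length(out) + 1L]] <<- list(env = m, name = nm,
                                       path = paste(path, nm, sep = "."))
    }
  })
  out
}

#' Count trainable parameters
#'
#' @param module a network or layer
#' @return total number of trainable scalar parameters
#' @export
nn_n_params <- function(module) {
  n <- 0L
  nn_walk(module, function(m, path) {
    for (p in m$par) n <<- n + length(p)
  })
  n
}

#' Extract all parameters and buffers as a flat named list
#'
#' The names are stable slash/dot paths (e.g. `"spatial1/conv.W"`), so a
#' state dict saved from one build can be loaded into another build of the
#' same configuration.
#'
#' @param module a network or layer
#' @return named list of numeric arrays
#' @export
nn_state_dict <- function(module) {
  sd <- list()
  nn_walk(module, function(m, path) {
    for (nm in names(m$par)) sd[[paste(path, nm, sep = ".")]] <<- m$par[[nm]]
    for (nm in names(m$buffers)) {
      sd[[paste(path, nm, sep = ".buf.")]] <<- m$buffers[[nm]]
    }
  })
  sd
}

#' Load a state dict produced by [nn_state_dict()]
#'
#' @param module a network or layer with the same architecture
#' @param state named list from [nn_state_dict()]
#' @return the module, invisibly
#' @export
nn_load_state_dict <- function(module, state) {
  seen <- character(0)
  nn_walk(module, function(m, path) {
    for (nm in names(m$par)) {
      key <- paste(path, nm, sep = ".")
      if (is.null(state[[key]])) stop("state dict is missing tensor ", key)
      if (length(state[[key]]) != length(m$par[[nm]])) {
        stop("state dict tensor ", key, " has the wrong size")
      }
      m$par[[nm]] <- state[[key]]
      seen <<- c(seen, key)
    }
    for (nm in names(m$buffers)) {
      key <- paste(path, nm, sep = ".buf.")
      if (!is.null(state[[key]])) m$buffers[[nm]] <- state[[key]]
    }
  })
  invisible(module)
}

#' Zero all accumulated gradients
#' @param module a network or layer
#' @return the module, invisibly
#' @export
nn_zero_grad <- function(module) {
  nn_walk(module, function(m, path) {
    for (nm in names(m$par)) {
      p <- m$par[[nm]]
      m$grad[[nm]] <- if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
    }
  })
  invisible(module)
}

# Count sub-modules of a given type (used by structural tests and summaries).
nn_count_type <- function(module, type) {
  n <- 0L
  nn_walk(module, function(m, path) if (m$type == type) n <<- n + 1L)
  n
}

# --- small shared helpers --------------------------------------------------

# Per-channel sums of a (B, C, H, W) array; returns length-C vector.
channel_sum <- function(x, B, C) {
  m <- x
  dim(m) <- c(B * C, length(x) / (B * C))
  .colSums(matrix(.rowSums(m, nrow(m), ncol(m)), B, C), B, C)
}

# Broadcast a length-C vector over a (B, C, ...) array laid out column-major:
# recycling a length-(B*C) vector down the rows of the (B*C, spatial) view.
channel_expand <- function(v, B) rep(v, each = B)

check_feature_map <- function(x, name = "x") {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop(name, " must be a rank-4 array with dim (batch, channels, height, width)")
  }
  invisible(dim(x))
}

.onLoad <- function(libname, pkgname) {
  # serial GEMMs: the batched layers call BLAS on many small matrices, where
  # thread fan-out costs more than it saves
  try(cpp_set_blas_threads(1L), silent = TRUE)
  invisible(NULL)
}
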