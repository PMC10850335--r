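#' @keywords internal
#' @useDynLib pmmnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Tape-based reverse-mode differentiation.
##
## Every tensor in a forward pass is an `ag_node`: an environment holding the
## numeric value, the parent nodes it was computed from, and a backward
## closure mapping the gradient at this node to gradients at its parents.
## Nodes are created eagerly in execution order, so decreasing creation id is
## a valid reverse-topological order and `ag_backward()` is a single sweep.
## The graph is rebuilt each forward pass (define-by-run); parameters are
## leaves flagged `requires = TRUE`.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_is_node <- function(x) inherits(x, "ag_node")

ag_node <- function(value, parents = list(), backward = NULL, requires = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  if (is.null(requires)) {
    requires <- length(parents) > 0L &&
      any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  }
  node$requires <- requires
  # backward closures are only kept where a gradient can actually flow
  if (requires) {
    node$parents <- parents
    node$backward <- backward
  } else {
    node$parents <- list()
    node$backward <- NULL
  }
  .ag$counter <- .ag$counter + 1L
  node$id <- .ag$counter
  class(node) <- "ag_node"
  node
}

ag_param <- function(value) ag_node(value, requires = TRUE)

ag_const <- function(value) ag_node(value, requires = FALSE)

as_ag <- function(x) if (ag_is_node(x)) x else ag_const(x)

ag_value <- function(x) if (ag_is_node(x)) x$value else x

#' @noRd
ag_backward <- function(root, seed_grad = NULL) {
  if (!ag_is_node(root)) stop("ag_backward() needs an ag_node", call. = FALSE)
  grads <- new.env(parent = emptyenv())
  if (is.null(seed_grad)) {
    if (length(root$value) != 1L) {
      stop("seed_grad required for non-scalar root", call. = FALSE)
    }
    seed_grad <- 1
  }
  assign(as.character(root$id), seed_grad, envir = grads)

  # collect reachable subgraph
  nodes <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!exists(key, envir = nodes, inherits = FALSE)) {
      assign(key, nd, envir = nodes)
      for (p in nd$parents) if (isTRUE(p$requires)) stack[[length(stack) + 1L]] <- p
    }
  }
  ids <- sort(as.integer(ls(nodes)), decreasing = TRUE)
  for (id in ids) {
    nd <- get(as.character(id), envir = nodes)
    key <- as.character(id)
    if (!exists(key, envir = grads, inherits = FALSE)) next
    g <- get(key, envir = grads)
    if (is.null(nd$backward)) next
    pgrads <- nd$backward(g)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!isTRUE(p$requires)) next
      pg <- pgrads[[i]]
      if (is.null(pg)) next
      pkey <- as.character(p$id)
      if (exists(pkey, envir = grads, inherits = FALSE)) {
        assign(pkey, get(pkey, envir = grads) + pg, envir = grads)
      } else {
        assign(pkey, pg, envir = grads)
      }
    }
  }
  grads
}

ag_grad <- function(grads, node) {
  key <- as.character(node$id)
  if (exists(key, envir = grads, inherits = FALSE)) {
    get(key, envir = grads)
  } else {
    array(0, dim(node$value) %||% length(node$value))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- elementwise ops -------------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_sigmoid <- function(a) {
  a <- as_ag(a)
  y <- sigmoid_stable(a$value)
  ag_node(y, list(a), function(g) list(g * y * (1 - y)))
}

ag_tanh <- function(a) {
  a <- as_ag(a)
  y <- tanh(a$value)
  ag_node(y, list(a), function(g) list(g * (1 - y * y)))
}

## numerically saturating logistic; exp(-x) may overflow to Inf for very
## negative x, in which case 1/(1+Inf) correctly underflows to 0
sigmoid_stable <- function(x) 1 / (1 + exp(-x))
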