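# Minimal reverse-mode tape. Values are dense R arrays (H, W, C, N), matrices
# or vectors; every op builds a node holding its value, its parent nodes and a
# vector-Jacobian product returning one gradient per parent (NULL for parents
# that need none). backward() accumulates into node$grad.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

ag_node <- function(value, parents = list(), vjp = NULL) {
  e <- new.env(parent = emptyenv())
  .ag$id <- .ag$id + 1L
  e$id <- .ag$id
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$vjp <- vjp
  class(e) <- "ag_node"
  e
}

#' @keywords internal
ag_param <- function(value) ag_node(value)

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

as_node <- function(x) if (inherits(x, "ag_node")) x else ag_node(x)

# iterative topological sort (post-order DFS)
ag_topo <- function(root) {
  order <- vector("list", 64L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L))
  assign(as.character(root$id), TRUE, envir = seen)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    node <- top$node
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      p <- node$parents[[top$i + 1L]]
      key <- as.character(p$id)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  order[seq_len(n_ord)]
}

ag_backward <- function(root, seed_grad = NULL) {
  topo <- ag_topo(root)
  root$grad <- if (is.null(seed_grad)) {
    v <- root$value
    if (length(v) != 1L) rds_numeric_error("backward() needs a scalar root or an explicit seed gradient")
    1
  } else seed_grad
  for (k in rev(seq_along(topo))) {
    node <- topo[[k]]
    if (is.null(node$vjp) || is.null(node$grad)) next
    gs <- node$vjp(node$grad)
    for (j in seq_along(node$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    node$grad <- NULL # interior gradient fully propagated; free it eagerly
  }
  invisible(root)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
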