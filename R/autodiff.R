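# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a numeric matrix wrapped in an environment
# ("ad_node").  Vector-Jacobian products are expressed through the same
# primitives, so gradients are themselves nodes and a second backward pass
# (needed for force-matching losses, where the force is already a gradient)
# is available for free.  Each primitive's vjp returns one *thunk* per
# parent; the backward pass evaluates a thunk only when that parent lies on
# a path to a requested differentiation target, so e.g. a coordinates-only
# backward never materializes parameter gradients.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_next_id <- function() {
  .ad$id <- .ad$id + 1L
  .ad$id
}

#' Create an autodiff tape node
#'
#' Wraps a numeric matrix as a node on the differentiation tape.  Users
#' normally call [ad_const()] or the operator helpers rather than this
#' directly.
#'
#' @param value numeric matrix (vectors are promoted to 1-column matrices).
#' @param parents list of parent `ad_node`s.
#' @param vjp function taking the incoming gradient node and returning a
#'   list of zero-argument thunks (one per parent), each producing that
#'   parent's gradient node when called.
#' @return an object of class `ad_node`.
#' @keywords internal
ad_node <- function(value, parents = list(), vjp = NULL) {
  if (!is.matrix(value)) value <- matrix(value, ncol = 1L)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$vjp <- vjp
  e$id <- ad_next_id()
  class(e) <- "ad_node"
  e
}

#' @rdname ad_node
#' @param x numeric matrix or vector.
#' @export
ad_const <- function(x) ad_node(x)

is_ad <- function(x) inherits(x, "ad_node")
as_ad <- function(x) if (is_ad(x)) x else ad_const(x)

#' @export
print.ad_node <- function(x, ...) {
  cat(sprintf("<ad_node %d: %d x %d>\n", x$id, nrow(x$value), ncol(x$value)))
  invisible(x)
}

#' Numeric value of a tape node
#' @param x an `ad_node`.
#' @return the underlying numeric matrix.
#' @export
ad_value <- function(x) x$value

## ---- primitives ----------------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value + b$value, list(a, b),
          function(g) list(function() g, function() g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value - b$value, list(a, b),
          function(g) list(function() g, function() ad_scale(g, -1)))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value * b$value, list(a, b),
          function(g) list(function() ad_mul(g, b),
                           function() ad_mul(g, a)))
}

# multiply by a plain scalar constant
ad_scale <- function(a, s) {
  a <- as_ad(a)
  ad_node(a$value * s, list(a), function(g) list(function() ad_scale(g, s)))
}

# add a plain constant (scalar or matrix, not differentiated)
ad_addc <- function(a, c) {
  a <- as_ad(a)
  ad_node(a$value + c, list(a), function(g) list(function() g))
}

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value %*% b$value, list(a, b),
          function(g) list(function() ad_matmul(g, ad_t(b)),
                           function() ad_matmul(ad_t(a), g)))
}

ad_t <- function(a) {
  a <- as_ad(a)
  ad_node(t(a$value), list(a), function(g) list(function() ad_t(g)))
}

# elementwise power with constant exponent; base must stay positive for
# non-integer p (true for the squared distances it is used on)
ad_pow <- function(a, p) {
  a <- as_ad(a)
  ad_node(a$value^p, list(a), function(g) {
    list(function() ad_mul(g, ad_scale(ad_pow(a, p - 1), p)))
  })
}

ad_exp <- function(a) {
  a <- as_ad(a)
  out <- ad_node(exp(a$value), list(a), NULL)
  out$vjp <- function(g) list(function() ad_mul(g, out))
  out
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  out <- ad_node(1 / (1 + exp(-a$value)), list(a), NULL)
  out$vjp <- function(g) {
    ## d sigma = sigma (1 - sigma)
    list(function() ad_mul(ad_mul(g, out), ad_addc(ad_scale(out, -1), 1)))
  }
  out
}

ad_sin <- function(a) {
  a <- as_ad(a)
  ad_node(sin(a$value), list(a),
          function(g) list(function() ad_mul(g, ad_cos(a))))
}

ad_cos <- function(a) {
  a <- as_ad(a)
  ad_node(cos(a$value), list(a),
          function(g) list(function() ad_scale(ad_mul(g, ad_sin(a)), -1)))
}

# row gather: out[k, ] = a[idx[k], ]; also serves as row broadcast
ad_gather <- function(a, idx) {
  a <- as_ad(a)
  n <- nrow(a$value)
  ad_node(a$value[idx, , drop = FALSE], list(a),
          function(g) list(function() ad_scatter(g, idx, n)))
}

# row scatter-add: out has n rows, out[i, ] = sum over k with idx[k] == i
ad_scatter <- function(a, idx, n) {
  a <- as_ad(a)
  val <- matrix(0, n, ncol(a$value))
  if (length(idx)) {
    agg <- rowsum(a$value, group = idx, reorder = TRUE)
    val[as.integer(rownames(agg)), ] <- agg
  }
  ad_node(val, list(a), function(g) list(function() ad_gather(g, idx)))
}

ad_cbind <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  na <- ncol(a$value); nb <- ncol(b$value)
  ad_node(cbind(a$value, b$value), list(a, b),
          function(g) list(function() ad_cols(g, 1L, na),
                           function() ad_cols(g, na + 1L, na + nb)))
}

# column slice [from..to]
ad_cols <- function(a, from, to) {
  a <- as_ad(a)
  nc <- ncol(a$value); nr <- nrow(a$value)
  ad_node(a$value[, from:to, drop = FALSE], list(a), function(g) {
    list(function() {
      left  <- if (from > 1L) ad_const(matrix(0, nr, from - 1L)) else NULL
      right <- if (to < nc)   ad_const(matrix(0, nr, nc - to))   else NULL
      out <- g
      if (!is.null(left))  out <- ad_cbind(left, out)
      if (!is.null(right)) out <- ad_cbind(out, right)
      out
    })
  })
}

ad_sum <- function(a) {
  a <- as_ad(a)
  nr <- nrow(a$value); nc <- ncol(a$value)
  ad_node(matrix(sum(a$value), 1L, 1L), list(a),
          function(g) list(function() ad_bcast(g, nr, nc)))
}

# broadcast a 1x1 node to nr x nc
ad_bcast <- function(a, nr, nc) {
  a <- as_ad(a)
  stopifnot(length(a$value) == 1L)
  ad_node(matrix(a$value[1L], nr, nc), list(a),
          function(g) list(function() ad_sum(g)))
}

# (E x k) -> (kE x 1), row-major flatten: rows stay contiguous
ad_vec_rows <- function(a) {
  a <- as_ad(a)
  k <- ncol(a$value)
  ad_node(matrix(as.vector(t(a$value)), ncol = 1L), list(a),
          function(g) list(function() ad_unvec_rows(g, k)))
}

# (kE x 1) -> (E x k), inverse of ad_vec_rows
ad_unvec_rows <- function(a, k) {
  a <- as_ad(a)
  ad_node(matrix(a$value, ncol = k, byrow = TRUE), list(a),
          function(g) list(function() ad_vec_rows(g)))
}

# fused affine map: x %*% W + row-broadcast bias b (1 x F)
ad_affine <- function(x, W, b) {
  x <- as_ad(x); W <- as_ad(W); b <- as_ad(b)
  val <- x$value %*% W$value
  if (nrow(val) > 0L)
    val <- val + matrix(b$value, nrow(val), ncol(val), byrow = TRUE)
  ad_node(val, list(x, W, b), function(g) {
    list(function() ad_matmul(g, ad_t(W)),
         function() ad_matmul(ad_t(x), g),
         function() ad_matmul(ad_const(matrix(1, 1L, nrow(g$value))), g))
  })
}

## ---- derived ops ---------------------------------------------------------

ad_neg <- function(a) ad_scale(a, -1)
ad_div <- function(a, b) ad_mul(a, ad_pow(b, -1))
ad_silu <- function(x) ad_mul(x, ad_sigmoid(x))

# sum over columns -> n x 1
ad_rowsum_cols <- function(a) {
  a <- as_ad(a)
  ad_matmul(a, ad_const(matrix(1, ncol(a$value), 1L)))
}

# broadcast an n x 1 column over nc columns
ad_bcast_cols <- function(a, nc) {
  a <- as_ad(a)
  ad_matmul(a, ad_const(matrix(1, 1L, nc)))
}

## ---- backward ------------------------------------------------------------

#' Reverse-mode gradients on the tape
#'
#' Computes gradients of a scalar (1x1) node `root` with respect to the
#' listed nodes.  The returned gradients are themselves tape nodes, so they
#' can be differentiated again (double backward).  Subgraphs that cannot
#' reach any requested target are never materialized.
#'
#' @param root an `ad_node` holding a single number.
#' @param wrt list of `ad_node`s to differentiate with respect to.
#' @param seed optional gradient seed node conforming to `root`'s shape.
#' @return list of `ad_node` gradients parallel to `wrt`; nodes unreachable
#'   from `root` get zero gradients.
#' @export
ad_grad <- function(root, wrt, seed = NULL) {
  if (is_ad(wrt)) wrt <- list(wrt)
  if (is.null(seed)) {
    stopifnot(length(root$value) == 1L)
    seed <- ad_const(matrix(1, 1L, 1L))
  }
  ## bookkeeping lives on the node environments under a per-call generation
  ## marker (string-keyed lookup tables would intern one symbol per node id
  ## forever, degrading the whole session)
  gen <- .ad$gen <- (if (is.null(.ad$gen)) 0L else .ad$gen) + 1L
  nodes <- vector("list", 256L)
  n_nodes <- 0L
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (identical(nd$.gen, gen)) next
    nd$.gen <- gen
    nd$.need <- FALSE
    nd$.grad <- NULL
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", n_nodes))
    nodes[[n_nodes]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(n_nodes)]
  nodes <- nodes[order(vapply(nodes, function(nd) nd$id, 0L))]
  for (w in wrt) {
    if (identical(w$.gen, gen)) w$.need <- TRUE
  }
  ## need: can a wrt target be reached by following parents?  parents always
  ## have smaller ids, so one increasing-id sweep suffices
  for (nd in nodes) {
    if (nd$.need) next
    for (p in nd$parents) {
      if (p$.need) {
        nd$.need <- TRUE
        break
      }
    }
  }
  root$.grad <- seed
  for (k in rev(seq_along(nodes))) {
    nd <- nodes[[k]]
    g <- nd$.grad
    if (is.null(g) || is.null(nd$vjp)) next
    thunks <- NULL
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!p$.need) next
      if (is.null(thunks)) thunks <- nd$vjp(g)
      pg <- thunks[[j]]()
      p$.grad <- if (is.null(p$.grad)) pg else ad_add(p$.grad, pg)
    }
  }
  out <- lapply(wrt, function(w) {
    g <- if (identical(w$.gen, gen)) w$.grad else NULL
    if (is.null(g)) ad_const(matrix(0, nrow(w$value), ncol(w$value))) else g
  })
  ## drop bookkeeping references so grad nodes do not pin the whole graph
  for (nd in nodes) nd$.grad <- NULL
  out
}
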