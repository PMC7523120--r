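# Reverse-mode automatic differentiation over dense matrices.
#
# All neural components in this package (encoder, flow conditioners, monotonic
# integrands, critic) are small dense networks trained by first-order ascent;
# this tape provides their gradients. Values are numeric matrices (rows =
# observations); constants may be plain numerics. A node is an environment
# holding the value, its accumulated gradient, its parents and a backward
# closure; the tape records creation order, which is a valid topological order
# for the reverse sweep.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

is_advar <- function(x) inherits(x, "advar")

#' @keywords internal
ad_value <- function(x) if (is_advar(x)) x$v else x

new_advar <- function(value, tape, parents = list(), bfun = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$parents <- parents
  nd$bfun <- bfun
  class(nd) <- "advar"
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd$id <- tape$n
  nd$tape <- tape
  nd
}

# Leaf (parameter or input) node.
ad_leaf <- function(value, tape) new_advar(value, tape)

# Generic op constructor: if no parent is on a tape, evaluate eagerly and
# return the plain value, so the same forward code serves prediction.
ad_op <- function(value, parents, bfun) {
  tape <- NULL
  for (p in parents) if (is_advar(p)) { tape <- p$tape; break }
  if (is.null(tape)) return(value)
  new_advar(value, tape, parents, bfun)
}

ad_backward <- function(node) {
  stopifnot(is_advar(node), length(node$v) == 1L)
  tape <- node$tape
  node$g <- matrix(1, 1, 1)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$g) || is.null(nd$bfun)) next
    gs <- nd$bfun(nd$g)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!is_advar(p) || is.null(gs[[k]])) next
      p$g <- if (is.null(p$g)) gs[[k]] else p$g + gs[[k]]
    }
  }
  invisible(node)
}

ad_grad <- function(node) {
  if (is.null(node$g)) array(0, dim(node$v)) else node$g
}

# --- primitive operations ----------------------------------------------------

ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_op(av %*% bv, list(a, b), function(g) {
    list(tcrossprod(g, bv), crossprod(av, g))
  })
}

# elementwise binary with scalar (length-1) broadcasting
.scal <- function(v) if (length(v) == 1L) as.numeric(v) else v
.bgrad <- function(g, x)
  if (length(ad_value(x)) == 1L) matrix(sum(g), 1L, 1L) else g

ad_add <- function(a, b) {
  av <- .scal(ad_value(a)); bv <- .scal(ad_value(b))
  ad_op(as_grad_shape(av + bv), list(a, b),
        function(g) list(.bgrad(g, a), .bgrad(g, b)))
}

ad_sub <- function(a, b) {
  av <- .scal(ad_value(a)); bv <- .scal(ad_value(b))
  ad_op(as_grad_shape(av - bv), list(a, b),
        function(g) list(.bgrad(g, a), -.bgrad(g, b)))
}

ad_mul <- function(a, b) {
  av <- .scal(ad_value(a)); bv <- .scal(ad_value(b))
  ad_op(as_grad_shape(av * bv), list(a, b), function(g) {
    ga <- g * bv; gb <- g * av
    list(if (length(av) == 1L) matrix(sum(ga), 1L, 1L) else ga,
         if (length(bv) == 1L) matrix(sum(gb), 1L, 1L) else gb)
  })
}

ad_div <- function(a, b) {
  av <- .scal(ad_value(a)); bv <- .scal(ad_value(b))
  ad_op(as_grad_shape(av / bv), list(a, b), function(g) {
    ga <- g / bv; gb <- -g * av / (bv * bv)
    list(if (length(av) == 1L) matrix(sum(ga), 1L, 1L) else ga,
         if (length(bv) == 1L) matrix(sum(gb), 1L, 1L) else gb)
  })
}

as_grad_shape <- function(v) if (is.matrix(v)) v else matrix(v, 1L)

ad_neg <- function(a) ad_op(-ad_value(a), list(a), function(g) list(-g))

# add a length-k bias row to every row of an n x k matrix
ad_addbias <- function(x, b) {
  xv <- ad_value(x); bv <- ad_value(b)
  ad_op(xv + rep(as.numeric(bv), each = nrow(xv)), list(x, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

# scale every row of an n x k matrix by a length-k weight row
ad_mulrow <- function(x, w) {
  xv <- ad_value(x); wv <- ad_value(w)
  wr <- rep(as.numeric(wv), each = nrow(xv))
  ad_op(xv * wr, list(x, w), function(g) {
    list(g * wr, matrix(colSums(g * xv), 1L))
  })
}

# sum `nblocks` equal-width column blocks of an n x (k*nblocks) matrix
ad_blocksum <- function(x, nblocks) {
  xv <- ad_value(x)
  k <- ncol(xv) / nblocks
  v <- xv[, seq_len(k), drop = FALSE]
  for (b in 2:nblocks) v <- v + xv[, (b - 1L) * k + seq_len(k), drop = FALSE]
  ad_op(v, list(x), function(g) list(g[, rep(seq_len(k), nblocks), drop = FALSE]))
}

# fold a list of (1 x k_i) pieces into one row
ad_cbind_list <- function(pieces) Reduce(ad_cbind2, pieces)

ad_exp <- function(a) {
  v <- exp(ad_value(a))
  ad_op(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  av <- ad_value(a)
  ad_op(log(av), list(a), function(g) list(g / av))
}

ad_tanh <- function(a) {
  v <- tanh(ad_value(a))
  ad_op(v, list(a), function(g) list(g * (1 - v * v)))
}

ad_sigmoid <- function(a) {
  v <- stats::plogis(ad_value(a))
  ad_op(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_softplus <- function(a) {
  av <- ad_value(a)
  v <- pmax(av, 0) + log1p(exp(-abs(av)))
  ad_op(v, list(a), function(g) list(g * stats::plogis(av)))
}

ad_pow <- function(a, k) {   # constant exponent
  av <- ad_value(a)
  ad_op(av^k, list(a), function(g) list(g * k * av^(k - 1)))
}

ad_sum <- function(a) {
  av <- ad_value(a)
  ad_op(matrix(sum(av), 1, 1), list(a),
        function(g) list(array(g[1L], dim(av))))
}

ad_mean <- function(a) {
  av <- ad_value(a)
  ad_op(matrix(mean(av), 1, 1), list(a),
        function(g) list(array(g[1L] / length(av), dim(av))))
}

ad_rowsums <- function(a) {
  av <- ad_value(a)
  ad_op(matrix(rowSums(av), ncol = 1L), list(a), function(g) {
    matrix(g, nrow(av), ncol(av)) |> list()
  })
}

# elementwise choice by a fixed 0/1 mask (no gradient through the mask)
ad_select <- function(mask, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_op(mask * av + (1 - mask) * bv, list(a, b), function(g) {
    ga <- g * mask; gb <- g * (1 - mask)
    list(if (length(av) == 1L) matrix(sum(ga), 1L, 1L) else ga,
         if (length(bv) == 1L) matrix(sum(gb), 1L, 1L) else gb)
  })
}

ad_clamp_max <- function(a, cap) {
  av <- ad_value(a)
  ad_op(pmin(av, cap), list(a), function(g) list(g * (av < cap)))
}

ad_cols <- function(a, idx) {
  av <- ad_value(a)
  ad_op(av[, idx, drop = FALSE], list(a), function(g) {
    out <- array(0, dim(av))
    if (anyDuplicated(idx)) {
      for (t in seq_along(idx)) out[, idx[t]] <- out[, idx[t]] + g[, t]
    } else {
      out[, idx] <- g
    }
    list(out)
  })
}

# tile all columns `times` times: value a[, rep(1:k, times)]; the gradient
# scatter-sum is a block sum
ad_coltile <- function(a, times) {
  av <- ad_value(a)
  k <- ncol(av)
  ad_op(av[, rep.int(seq_len(k), times), drop = FALSE], list(a), function(g) {
    out <- g[, seq_len(k), drop = FALSE]
    for (b in 2:times)
      out <- out + g[, (b - 1L) * k + seq_len(k), drop = FALSE]
    list(out)
  })
}

# gather columns of a one-row matrix by index (duplicates allowed)
ad_colgather <- function(a, idx) {
  av <- ad_value(a)
  ad_op(av[, idx, drop = FALSE], list(a), function(g) {
    list(matrix(rowsum(as.numeric(g), idx), 1L))
  })
}

# fused v = tanh(x * w_row + b_row); one stored intermediate
ad_tanh_rowaff <- function(x, w, b) {
  xv <- ad_value(x)
  wr <- rep(as.numeric(ad_value(w)), each = nrow(xv))
  v <- tanh(xv * wr + rep(as.numeric(ad_value(b)), each = nrow(xv)))
  ad_op(v, list(x, w, b), function(g) {
    u <- g * (1 - v * v)
    list(u * wr, matrix(colSums(u * xv), 1L), matrix(colSums(u), 1L))
  })
}

ad_reshape <- function(a, nrow, ncol) {
  av <- ad_value(a)
  ad_op(matrix(as.vector(av), nrow, ncol), list(a), function(g) {
    list(matrix(as.vector(g), dim(av)[1L], dim(av)[2L]))
  })
}
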