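# Reverse-mode autodiff over dense matrices.
#
# Every network and loss in the package is written against the `op_*` helpers
# below, which dispatch on whether an argument is a tape node (an environment
# created by `ad_node()`) or a plain matrix. Called with plain matrices they
# are ordinary base-R matrix arithmetic; called with nodes they record the
# operation on a tape so `ad_backward()` can accumulate gradients. A fresh
# tape is created for every optimisation step. The implementation favours low
# per-operation overhead (nodes are bare environments, dispatch is a single
# `is.environment()` test) because networks here are small and shallow: R-level
# bookkeeping, not matrix algebra, is the cost that matters.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 1024L)
  t$n <- 0L
  t
}

ad_is_node <- function(x) is.environment(x)

ad_node <- function(tape, value, vjp = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$vjp <- vjp
  n$tape <- tape
  k <- tape$n + 1L
  if (k > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[k]] <- n
  tape$n <- k
  n
}

#' @noRd
ad_param <- function(tape, value) ad_node(tape, value)

ad_value <- function(x) if (is.environment(x)) x$value else x

# accumulate gradient g into node (no-op for plain matrices / constants)
ad_acc <- function(x, g) {
  if (is.environment(x)) {
    x$grad <- if (is.null(x$grad)) g else x$grad + g
  }
  invisible(NULL)
}

# run the backward pass from a scalar (1 x 1) output node
ad_backward <- function(out) {
  stopifnot(is.environment(out))
  tape <- out$tape
  out$grad <- matrix(1, 1, 1)
  nodes <- tape$nodes
  for (i in seq(tape$n, 1L)) {
    nd <- nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$vjp)) nd$vjp(nd$grad)
  }
  invisible(NULL)
}

tape2 <- function(a, b) {
  if (is.environment(a)) a$tape else if (is.environment(b)) b$tape else NULL
}

# ---- primitive operations ----------------------------------------------------

op_mm <- function(a, b) {
  tp <- tape2(a, b)
  av <- if (is.environment(a)) a$value else a
  bv <- if (is.environment(b)) b$value else b
  v <- av %*% bv
  if (is.null(tp)) return(v)
  ad_node(tp, v, function(g) {
    ad_acc(a, tcrossprod(g, bv))
    ad_acc(b, crossprod(av, g))
  })
}

op_add <- function(a, b) {
  tp <- tape2(a, b)
  av <- if (is.environment(a)) a$value else a
  bv <- if (is.environment(b)) b$value else b
  v <- av + bv
  if (is.null(tp)) return(v)
  ad_node(tp, v, function(g) { ad_acc(a, g); ad_acc(b, g) })
}

# add a length-k bias vector to every row of an N x k matrix
op_addb <- function(a, b) {
  tp <- tape2(a, b)
  av <- if (is.environment(a)) a$value else a
  bv <- if (is.environment(b)) b$value else b
  v <- av + rep(bv, each = nrow(av))
  if (is.null(tp)) return(v)
  ad_node(tp, v, function(g) { ad_acc(a, g); ad_acc(b, colSums(g)) })
}

op_sub <- function(a, b) {
  tp <- tape2(a, b)
  av <- if (is.environment(a)) a$value else a
  bv <- if (is.environment(b)) b$value else b
  v <- av - bv
  if (is.null(tp)) return(v)
  ad_node(tp, v, function(g) { ad_acc(a, g); ad_acc(b, -g) })
}

op_mul <- function(a, b) {
  tp <- tape2(a, b)
  av <- if (is.environment(a)) a$value else a
  bv <- if (is.environment(b)) b$value else b
  v <- av * bv
  if (is.null(tp)) return(v)
  ad_node(tp, v, function(g) { ad_acc(a, g * bv); ad_acc(b, g * av) })
}

op_scale <- function(a, k) {
  if (!is.environment(a)) return(a * k)
  v <- a$value * k
  ad_node(a$tape, v, function(g) ad_acc(a, g * k))
}

op_sigmoid <- function(a) {
  if (!is.environment(a)) return(plogis(a))
  v <- plogis(a$value)
  ad_node(a$tape, v, function(g) ad_acc(a, g * v * (1 - v)))
}

op_tanh <- function(a) {
  if (!is.environment(a)) return(tanh(a))
  v <- tanh(a$value)
  ad_node(a$tape, v, function(g) ad_acc(a, g * (1 - v * v)))
}

op_log <- function(a) {
  if (!is.environment(a)) return(log(a))
  v <- log(a$value)
  av <- a$value
  ad_node(a$tape, v, function(g) ad_acc(a, g / av))
}

op_exp <- function(a) {
  if (!is.environment(a)) return(exp(a))
  v <- exp(a$value)
  ad_node(a$tape, v, function(g) ad_acc(a, g * v))
}

# sqrt with an epsilon guard so the gradient stays finite at zero; eps = 0
# gives the exact value (used on the plain, non-tape path).
op_sqrt <- function(a, eps = 0) {
  if (!is.environment(a)) return(sqrt(a + eps))
  v <- sqrt(a$value + eps)
  ad_node(a$tape, v, function(g) ad_acc(a, g / (2 * v)))
}

op_sum <- function(a) {
  if (!is.environment(a)) return(matrix(sum(a), 1, 1))
  av <- a$value
  v <- matrix(sum(av), 1, 1)
  ad_node(a$tape, v, function(g) ad_acc(a, matrix(g[1], nrow(av), ncol(av))))
}

op_rowsums <- function(a) {
  if (!is.environment(a)) return(matrix(rowSums(a), ncol = 1))
  av <- a$value
  v <- matrix(rowSums(av), ncol = 1)
  ad_node(a$tape, v, function(g) ad_acc(a, matrix(g, nrow(av), ncol(av))))
}

op_cbind <- function(a, b) {
  tp <- tape2(a, b)
  av <- if (is.environment(a)) a$value else a
  bv <- if (is.environment(b)) b$value else b
  v <- cbind(av, bv)
  if (is.null(tp)) return(v)
  ka <- ncol(av)
  ad_node(tp, v, function(g) {
    ad_acc(a, g[, seq_len(ka), drop = FALSE])
    ad_acc(b, g[, -seq_len(ka), drop = FALSE])
  })
}

op_cols <- function(a, idx) {
  if (!is.environment(a)) return(a[, idx, drop = FALSE])
  av <- a$value
  v <- av[, idx, drop = FALSE]
  ad_node(a$tape, v, function(g) {
    z <- matrix(0, nrow(av), ncol(av))
    z[, idx] <- g
    ad_acc(a, z)
  })
}

op_rows <- function(a, idx) {
  if (!is.environment(a)) return(a[idx, , drop = FALSE])
  av <- a$value
  v <- av[idx, , drop = FALSE]
  ad_node(a$tape, v, function(g) {
    z <- matrix(0, nrow(av), ncol(av))
    z[idx, ] <- g
    ad_acc(a, z)
  })
}

# row-wise softmax (used per categorical block in the decoders)
op_softmax <- function(a) {
  av <- if (is.environment(a)) a$value else a
  m <- av - apply(av, 1, max)
  e <- exp(m)
  v <- e / rowSums(e)
  if (!is.environment(a)) return(v)
  ad_node(a$tape, v, function(g) ad_acc(a, v * (g - rowSums(g * v))))
}

op_div <- function(a, b) {
  tp <- tape2(a, b)
  av <- if (is.environment(a)) a$value else a
  bv <- if (is.environment(b)) b$value else b
  v <- av / bv
  if (is.null(tp)) return(v)
  ad_node(tp, v, function(g) {
    ad_acc(a, g / bv)
    ad_acc(b, -g * av / (bv * bv))
  })
}

# numerically stable log(sigmoid(x)) = -log1p(exp(-x))
op_logsigmoid <- function(a) {
  av <- if (is.environment(a)) a$value else a
  v <- ifelse(av > 0, -log1p(exp(-av)), av - log1p(exp(av)))
  if (!is.environment(a)) return(v)
  ad_node(a$tape, v, function(g) ad_acc(a, g * plogis(-av)))
}

op_clamp <- function(a, lo, hi) {
  av <- if (is.environment(a)) a$value else a
  v <- pmin(pmax(av, lo), hi)
  if (!is.environment(a)) return(v)
  inside <- (av > lo & av < hi) * 1
  ad_node(a$tape, v, function(g) ad_acc(a, g * inside))
}
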