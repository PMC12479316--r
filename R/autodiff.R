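# Reverse-mode automatic differentiation on a dynamic tape.
#
# Nodes are environments holding a value (numeric scalar, matrix or 3-d
# array), a list of parent nodes and a backward closure mapping the node's
# output gradient to per-parent gradients. Graphs are built define-by-run:
# every forward pass constructs a fresh tape, so control flow in R code is
# differentiated for free. Only the operations the pressure-translation
# models need are implemented.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_node <- function(value, parents = list(), backfn = NULL) {
  force(value)
  force(parents)
  .ad_env$counter <- .ad_env$counter + 1L
  n <- new.env(parent = emptyenv())
  n$id <- .ad_env$counter
  n$value <- value
  n$parents <- parents
  n$backfn <- backfn
  n$grad <- NULL
  n$requires <- length(parents) > 0L &&
    any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  class(n) <- "ad_node"
  n
}

# Leaf wrappers: gradients are only propagated into subgraphs reachable from
# ad_param leaves; ad_const subtrees are skipped during backward.
ad_const <- function(x) ad_node(x)
ad_param <- function(x) {
  n <- ad_node(x)
  n$requires <- TRUE
  n
}

ad_value <- function(n) n$value
ad_grad <- function(n) {
  if (is.null(n$grad)) array(0, dim = dim_of(n$value)) else n$grad
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

zeros_like <- function(x) {
  if (is.null(dim(x))) numeric(length(x)) else array(0, dim = dim(x))
}

.accum_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' @noRd
ad_backward <- function(root) {
  stopifnot(inherits(root, "ad_node"), length(root$value) == 1L)
  # iterative post-order DFS over parent edges: in the reversed order every
  # node appears before its parents, so its gradient is complete when its
  # backward closure runs
  seen <- new.env(parent = emptyenv())
  post <- vector("list", 256L)
  np <- 0L
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- top$node
    key <- as.character(n$id)
    if (top$expanded) {
      np <- np + 1L
      if (np > length(post)) post <- c(post, vector("list", length(post)))
      post[[np]] <- n
      next
    }
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    stack[[length(stack) + 1L]] <- list(node = n, expanded = TRUE)
    for (p in n$parents) {
      if (is.null(seen[[as.character(p$id)]])) {
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
      }
    }
  }
  post <- post[seq_len(np)]
  for (n in post) n$grad <- NULL
  root$grad <- 1
  for (n in rev(post)) {
    if (is.null(n$backfn) || is.null(n$grad) || !isTRUE(n$requires)) next
    gs <- n$backfn(n$grad)
    for (k in seq_along(gs)) {
      if (!is.null(gs[[k]]) && isTRUE(n$parents[[k]]$requires)) {
        .accum_grad(n$parents[[k]], gs[[k]])
      }
    }
  }
  invisible(root)
}

.as_node <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

# ---- elementwise arithmetic ------------------------------------------------

# reduce gradient g to the shape of value v (handles scalar broadcast)
.reduce_to <- function(g, v) {
  if (length(v) == 1L) sum(g) else g
}

ad_add <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  ad_node(a$value + b$value, list(a, b), function(g) {
    list(.reduce_to(g, a$value), .reduce_to(g, b$value))
  })
}

ad_sub <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  ad_node(a$value - b$value, list(a, b), function(g) {
    list(.reduce_to(g, a$value), .reduce_to(-g, b$value))
  })
}

ad_mul <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  ad_node(a$value * b$value, list(a, b), function(g) {
    list(.reduce_to(g * b$value, a$value), .reduce_to(g * a$value, b$value))
  })
}

ad_div <- function(a, b) {
  a <- .as_node(a); b <- .as_node(b)
  ad_node(a$value / b$value, list(a, b), function(g) {
    list(.reduce_to(g / b$value, a$value),
         .reduce_to(-g * a$value / (b$value^2), b$value))
  })
}

ad_scale <- function(a, k) {
  ad_node(a$value * k, list(a), function(g) list(g * k))
}

ad_addc <- function(a, k) {
  ad_node(a$value + k, list(a), function(g) list(g))
}

ad_neg <- function(a) ad_scale(a, -1)

ad_square <- function(a) ad_mul(a, a)

# ---- reductions ------------------------------------------------------------

ad_sum <- function(a) {
  ad_node(sum(a$value), list(a), function(g) {
    list(array(g, dim = dim_of(a$value)))
  })
}

ad_mean <- function(a) {
  n <- length(a$value)
  ad_node(mean(a$value), list(a), function(g) {
    list(array(g / n, dim = dim_of(a$value)))
  })
}

# ---- nonlinearities --------------------------------------------------------

ad_log <- function(a) {
  ad_node(log(a$value), list(a), function(g) list(g / a$value))
}

ad_exp <- function(a) {
  y <- exp(a$value)
  ad_node(y, list(a), function(g) list(g * y))
}

ad_sqrt <- function(a) {
  y <- sqrt(a$value)
  ad_node(y, list(a), function(g) list(g * 0.5 / y))
}

ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  ad_node(y, list(a), function(g) list(g * y * (1 - y)))
}

ad_relu <- function(a) {
  m <- a$value > 0
  ad_node(a$value * m, list(a), function(g) list(g * m))
}

ad_lrelu <- function(a, alpha = 0.2) {
  m <- a$value > 0
  y <- ifelse(m, a$value, alpha * a$value)
  if (!is.null(dim(a$value))) dim(y) <- dim(a$value)
  ad_node(y, list(a), function(g) list(g * ifelse(m, 1, alpha)))
}

ad_clamp <- function(a, lo, hi) {
  m <- a$value >= lo & a$value <= hi
  y <- pmin(pmax(a$value, lo), hi)
  if (!is.null(dim(a$value))) dim(y) <- dim(a$value)
  ad_node(y, list(a), function(g) list(g * m))
}

# ---- linear algebra --------------------------------------------------------

ad_matmul <- function(a, b) {
  ad_node(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# add a length-d vector to every row of an n x d matrix
ad_add_rowvec <- function(m, v) {
  y <- sweep(m$value, 2L, v$value, "+")
  ad_node(y, list(m, v), function(g) list(g, colSums(g)))
}

ad_transpose <- function(m) {
  ad_node(t(m$value), list(m), function(g) list(t(g)))
}

ad_reshape <- function(a, dm) {
  od <- dim_of(a$value)
  y <- a$value
  dim(y) <- dm
  ad_node(y, list(a), function(g) {
    dim(g) <- if (length(od) == 1L) NULL else od
    list(g)
  })
}

ad_cols <- function(m, idx) {
  ad_node(m$value[, idx, drop = FALSE], list(m), function(g) {
    out <- zeros_like(m$value)
    out[, idx] <- g
    list(out)
  })
}

ad_cbind <- function(parts) {
  widths <- vapply(parts, function(p) ncol(p$value), integer(1))
  y <- do.call(cbind, lapply(parts, ad_value))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(y, parts, function(g) {
    lapply(seq_along(parts), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

# concatenate two H x W x C arrays along the channel axis
ad_concat_ch <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[1:2] == db[1:2]))
  y <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3] + db[3]))
  ad_node(y, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# ---- softmax / layer norm --------------------------------------------------

ad_softmax_rows <- function(m) {
  x <- m$value
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  y <- e / rowSums(e)
  ad_node(y, list(m), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

# layer normalization over each row of an n x d matrix with learned scale
# and shift (length-d vectors)
ad_layernorm <- function(m, gamma, beta, eps = 1e-5) {
  x <- m$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  ad_node(y, list(m, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gamma$value, "*")
    # per-row backward through the normalization
    t1 <- rowSums(dxhat)
    t2 <- rowSums(dxhat * xhat)
    dx <- inv * (dxhat - t1 / d - xhat * t2 / d)
    list(dx, colSums(g * xhat), colSums(g))
  })
}
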