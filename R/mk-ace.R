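#' Two-state equal-rates transition probabilities
#'
#' For the symmetric (equal-rates) two-state Markov model with rate `q`,
#' the probability of staying in the current state over a branch of length
#' `t` is `(1 + exp(-2 q t)) / 2` and of switching `(1 - exp(-2 q t)) / 2`.
#' Rows index the starting state (`0`, `1`), columns the ending state, and
#' each row sums to 1. `q = 0` or `t = 0` gives the identity table; as
#' `q t` grows the table approaches the stationary 0.5 everywhere.
#'
#' @param q Transition rate (events per unit branch length), `>= 0`.
#' @param t Branch length, `>= 0`.
#' @return A 2x2 numeric matrix with dimnames `c("0", "1")`.
#' @export
#' @examples
#' er_transition(0.5, 1)  # P(switch) = (1 - exp(-1)) / 2
er_transition <- function(q, t) {
  stopifnot(q >= 0, t >= 0)
  sw <- (1 - exp(-2 * q * t)) / 2
  matrix(c(1 - sw, sw, sw, 1 - sw), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# coerce tip states (named vector, or tibble with id/state) to a named
# integer vector in {0, 1} covering every tip of the tree
as_tip_states <- function(tree, tip_states) {
  if (is.data.frame(tip_states)) {
    tip_states <- stats::setNames(tip_states$state, tip_states$id)
  }
  if (is.null(names(tip_states))) {
    stop("tip_states must be named by tip label", call. = FALSE)
  }
  missing_tips <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing_tips) > 0L) {
    stop("no state for tip(s): ", paste(utils::head(missing_tips, 5),
                                        collapse = ", "), call. = FALSE)
  }
  st <- as.integer(tip_states[tree$tip.label])
  if (!all(st %in% c(0L, 1L))) {
    stop("tip states must be 0 or 1", call. = FALSE)
  }
  stats::setNames(st, tree$tip.label)
}

check_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative", call. = FALSE)
  }
  invisible(tree)
}

# scaled post-order partial likelihoods; returns the per-node scaled
# partials, the accumulated log scaling factor, and the postorder tree
er_partials <- function(tree, states, q) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  L <- matrix(1, nt + nn, 2)
  L[seq_len(nt), ] <- 0
  L[cbind(seq_len(nt), states[tree$tip.label] + 1L)] <- 1
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- tr$edge
  el <- tr$edge.length
  log_scale <- 0
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1L]
    ch <- E[i, 2L]
    Lc <- L[ch, ]
    s <- Lc[1L] + Lc[2L]
    if (s <= 0) {
      # data impossible under this q (e.g. q = 0 with conflicting tips)
      return(list(L = L, log_scale = -Inf, tree = tr, n_tip = nt,
                  impossible = TRUE))
    }
    Lc <- Lc / s
    log_scale <- log_scale + log(s)
    P <- er_transition(q, el[i])
    L[p, ] <- L[p, ] * (P %*% Lc)[, 1L]
  }
  list(L = L, log_scale = log_scale, tree = tr, n_tip = nt)
}

#' Pruning log-likelihood of a binary character under the ER-Mk model
#'
#' Felsenstein's post-order pruning recursion with per-node scaling (so
#' likelihoods stay representable on trees with thousands of tips),
#' combined at the root with `root_prior`. Polytomies and zero-length
#' branches are handled without modification.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param tip_states Named 0/1 vector by tip label, or a tibble with
#'   columns `id` and `state`.
#' @param q ER transition rate.
#' @param root_prior Root state prior; default uniform `c(0.5, 0.5)`, the
#'   ER stationary distribution.
#' @return The natural-log likelihood (scalar).
#' @export
mk_er_loglik <- function(tree, tip_states, q, root_prior = c(0.5, 0.5)) {
  check_tree(tree)
  stopifnot(q >= 0, length(root_prior) == 2L,
            abs(sum(root_prior) - 1) < 1e-9)
  states <- as_tip_states(tree, tip_states)
  pr <- er_partials(tree, states, q)
  if (isTRUE(pr$impossible)) return(-Inf)
  root <- pr$n_tip + 1L
  log(sum(root_prior * pr$L[root, ])) + pr$log_scale
}

#' Fit the ER-Mk rate by maximum likelihood
#'
#' One-dimensional bounded maximization of [mk_er_loglik()] over
#' `q` in `[1e-8, q_max]` with `q_max = 100 / mean(branch length)`,
#' converged to `1e-8` on `q`. When every tip shares the same state the
#' likelihood is maximized at the no-change boundary: `q_hat` is pinned
#' at the lower bound and the fit is flagged.
#'
#' @inheritParams mk_er_loglik
#' @return An object of class `mk_er_fit`: list with `q_hat`, `loglik`,
#'   `boundary` (logical), `n_tips`, plus the inputs needed by
#'   [ancestral_states()].
#' @export
#' @seealso [ancestral_states()], [tidy.mk_er_fit()], [glance.mk_er_fit()]
fit_mk_er <- function(tree, tip_states, root_prior = c(0.5, 0.5)) {
  check_tree(tree)
  states <- as_tip_states(tree, tip_states)
  if (length(states) < 2L) stop("need at least 2 tips", call. = FALSE)
  q_lo <- 1e-8
  q_hi <- 100 / mean(tree$edge.length)
  if (length(unique(states)) == 1L) {
    q_hat <- q_lo
    boundary <- TRUE
  } else {
    # the profile flattens onto the saturation plateau at large q, which can
    # strand a plain golden-section search; bracket the optimum on a coarse
    # log-spaced grid first, then refine within the bracketing interval
    f <- function(q) mk_er_loglik(tree, states, q, root_prior)
    grid <- exp(seq(log(q_lo), log(q_hi), length.out = 40L))
    ll <- vapply(grid, f, numeric(1))
    k <- which.max(ll)
    lo <- grid[max(1L, k - 1L)]
    hi <- grid[min(length(grid), k + 1L)]
    opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
    q_hat <- opt$maximum
    boundary <- FALSE
  }
  structure(
    list(
      q_hat = q_hat,
      loglik = mk_er_loglik(tree, states, q_hat, root_prior),
      boundary = boundary,
      n_tips = length(states),
      tree = tree,
      tip_states = states,
      root_prior = root_prior,
      interval = c(q_lo, q_hi)
    ),
    class = "mk_er_fit"
  )
}

#' @export
print.mk_er_fit <- function(x, ...) {
  cat(sprintf("ER-Mk fit: q_hat = %.6g, logLik = %.4f, %d tips%s\n",
              x$q_hat, x$loglik, x$n_tips,
              if (x$boundary) " (boundary: all tips identical)" else ""))
  invisible(x)
}

#' @rdname tidy.dcr_clustering
#' @method tidy mk_er_fit
#' @export
tidy.mk_er_fit <- function(x, ...) {
  tibble::tibble(term = "q", estimate = x$q_hat, boundary = x$boundary)
}

#' @rdname glance.dcr_clustering
#' @method glance mk_er_fit
#' @export
glance.mk_er_fit <- function(x, ...) {
  tibble::tibble(q_hat = x$q_hat, logLik = x$loglik, n_tips = x$n_tips,
                 boundary = x$boundary)
}

#' Marginal ancestral state reconstruction
#'
#' For each internal node the marginal posterior of its state given every
#' tip is proportional to the product of the partial likelihood of the
#' subtree below the node and the "outside" likelihood contributed by the
#' rest of the tree (computed by a pre-order message pass, equivalent to
#' re-rooting at each node; the ER model is reversible so the two views
#' agree). Probabilities are normalized per node.
#'
#' @param fit An `mk_er_fit`, or a tree (then `tip_states` and `q` must be
#'   given).
#' @param tip_states,q,root_prior Used only when `fit` is a tree.
#' @return Tibble with one row per internal node: `node` (ape node index),
#'   `label` (node label or `Node<k>`), `p0`, `p1` (posterior
#'   probabilities of canonical-PAZ absence/presence, summing to 1).
#' @export
ancestral_states <- function(fit, tip_states = NULL, q = NULL,
                             root_prior = c(0.5, 0.5)) {
  if (inherits(fit, "mk_er_fit")) {
    tree <- fit$tree
    states <- fit$tip_states
    q <- fit$q_hat
    root_prior <- fit$root_prior
  } else {
    tree <- check_tree(fit)
    states <- as_tip_states(tree, tip_states)
    stopifnot(!is.null(q))
  }
  pr <- er_partials(tree, states, q)
  if (isTRUE(pr$impossible)) {
    stop("tip data have zero likelihood at this q", call. = FALSE)
  }
  L <- pr$L
  tr <- pr$tree
  nt <- pr$n_tip
  nn <- tree$Nnode
  root <- nt + 1L
  E <- tr$edge
  el <- tr$edge.length

  # children edge indices per parent node
  kids <- split(seq_len(nrow(E)), E[, 1L])
  # per-edge downward message: P(t_i) %*% scaled L[child_i, ]
  msg <- matrix(0, nrow(E), 2)
  for (i in seq_len(nrow(E))) {
    Lc <- L[E[i, 2L], ]
    Lc <- Lc / sum(Lc)
    msg[i, ] <- (er_transition(q, el[i]) %*% Lc)[, 1L]
  }

  # pre-order upward pass: U[n, ] is the outside likelihood at node n
  U <- matrix(0, nt + nn, 2)
  U[root, ] <- root_prior
  for (i in rev(seq_len(nrow(E)))) {         # reverse postorder = preorder
    p <- E[i, 1L]
    ch <- E[i, 2L]
    sib <- setdiff(kids[[as.character(p)]], i)
    prod_sib <- U[p, ]
    for (j in sib) prod_sib <- prod_sib * msg[j, ]
    up <- crossprod(er_transition(q, el[i]), prod_sib)[, 1L]
    U[ch, ] <- up / sum(up)
  }

  internal <- root:(nt + nn)
  post <- L[internal, , drop = FALSE] * U[internal, , drop = FALSE]
  post <- post / rowSums(post)
  labels <- tree$node.label %||% paste0("Node", seq_len(nn))
  labels[!nzchar(labels)] <- paste0("Node", seq_len(nn))[!nzchar(labels)]
  tibble::tibble(
    node = internal,
    label = labels,
    p0 = post[, 1L],
    p1 = post[, 2L]
  )
}

#' Read a tip-state table
#'
#' TSV with columns `id` and `state` (0 = canonical PAZ absent,
#' 1 = present).
#'
#' @param path File path.
#' @return Tibble with `id`, `state`.
#' @export
read_tip_states <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), state = readr::col_integer()
  ))
}
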