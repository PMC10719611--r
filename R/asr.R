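## Ancestral state reconstruction of a binary trait (tolerant /
## susceptible) on a fixed tree under a symmetric two-state
## continuous-time Markov chain with a uniform ("null") root
## distribution: Felsenstein pruning, exact marginal posteriors, a
## Bayesian MCMC over the exchange rate, and Sankoff parsimony loss
## counting.

#' Trait states, in the order used by all reconstruction output
#' @export
TRAIT_STATES <- c("tolerant", "susceptible")

#' Transition probabilities of the symmetric two-state chain
#'
#' `P(stay) = 1/2 + exp(-2 r t)/2`, `P(switch) = 1/2 - exp(-2 r t)/2`.
#'
#' @param r exchange rate (> 0).
#' @param t branch length (>= 0).
#' @return 2 x 2 stochastic matrix over [TRAIT_STATES].
#' @export
transition_probability <- function(r, t) {
  if (r <= 0) stop("rate must be positive")
  if (t < 0) stop("negative branch length")
  e <- exp(-2 * r * t)
  matrix(c(0.5 + 0.5 * e, 0.5 - 0.5 * e,
           0.5 - 0.5 * e, 0.5 + 0.5 * e), 2L, 2L,
         dimnames = list(TRAIT_STATES, TRAIT_STATES))
}

## One-hot tip likelihoods (rows ordered by tip number). Errors on tips
## with no (or missing) state.
.tip_likelihoods <- function(tree, traits) {
  tips <- tree$tip.label
  st <- traits[tips]
  if (any(is.na(st)))
    stop("leaf without state: ",
         paste(tips[is.na(st)], collapse = ", "),
         " (prune_to_scored() first)")
  bad <- setdiff(unique(st), TRAIT_STATES)
  if (length(bad)) stop("unknown states: ", paste(bad, collapse = ", "))
  cbind(as.numeric(st == TRAIT_STATES[1L]), as.numeric(st == TRAIT_STATES[2L]))
}

## Postorder up pass. Returns log-likelihood, per-node partials (scaled,
## scale cancels within a node) and per-edge messages to the parent.
.up_pass <- function(tree, tipL, r, root_dist) {
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  ntot <- ape::Ntip(tree) + ape::Nnode(tree)
  L <- matrix(1, ntot, 2L)
  L[seq_len(ape::Ntip(tree)), ] <- tipL
  msg <- matrix(NA_real_, nrow(tree$edge), 2L)
  logscale <- 0
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    e <- exp(-2 * r * tree$edge.length[k])
    s <- 0.5 + 0.5 * e; w <- 0.5 - 0.5 * e
    m1 <- s * L[ch, 1L] + w * L[ch, 2L]
    m2 <- w * L[ch, 1L] + s * L[ch, 2L]
    msg[k, ] <- c(m1, m2)
    L[p, 1L] <- L[p, 1L] * m1
    L[p, 2L] <- L[p, 2L] * m2
    mx <- max(L[p, ])
    if (mx > 0 && mx < 1e-150) {
      L[p, ] <- L[p, ] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- tree$edge[nrow(tree$edge), 1L]
  lik <- sum(root_dist * L[root, ])
  list(tree = tree, L = L, msg = msg, root = root,
       loglik = log(lik) + logscale)
}

#' Log-likelihood of tip states under the symmetric two-state chain
#'
#' Felsenstein pruning with the root partials summed against the root
#' distribution (uniform by default).
#'
#' @param tree `phylo` with branch lengths; every leaf must have a state.
#' @param traits named character vector of [TRAIT_STATES] over the tips.
#' @param r exchange rate.
#' @param root_dist root state distribution over
#'   (tolerant, susceptible); default uniform.
#' @export
pruning_likelihood <- function(tree, traits, r, root_dist = c(0.5, 0.5)) {
  if (r <= 0) stop("rate must be positive")
  .up_pass(tree, .tip_likelihoods(tree, traits), r, root_dist)$loglik
}

#' Maximum-likelihood exchange rate
#'
#' One-dimensional bounded optimization of [pruning_likelihood()] over
#' `log r`, bounds `[1e-6, 1e3]`, tolerance `1e-8`.
#'
#' @inheritParams pruning_likelihood
#' @return the rate estimate, with attributes `loglik` and `boundary`.
#' @export
mle_rate <- function(tree, traits, root_dist = c(0.5, 0.5)) {
  tipL <- .tip_likelihoods(tree, traits)
  if (length(unique(traits[tree$tip.label])) == 1L) {
    warning("all tips share one state; rate estimate at lower bound")
    return(structure(1e-6, loglik = 0, boundary = TRUE))
  }
  f <- function(lr) -.up_pass(tree, tipL, exp(lr), root_dist)$loglik
  opt <- optimize(f, c(log(1e-6), log(1e3)), tol = 1e-8)
  r <- exp(opt$minimum)
  boundary <- opt$minimum < log(1e-6) + 1e-4 || opt$minimum > log(1e3) - 1e-4
  if (boundary) warning("rate estimate at optimization boundary")
  structure(r, loglik = -opt$objective, boundary = boundary)
}

#' Exact marginal ancestral state probabilities
#'
#' Up-down (inside-outside) pass yielding, for every internal node, the
#' exact posterior probability of each state given the tips, the rate and
#' the root distribution.
#'
#' @inheritParams pruning_likelihood
#' @return object of class `asr`: posterior matrix (internal nodes x
#'   states), rate, log-likelihood, method `"marginal"`.
#' @export
marginal_asr <- function(tree, traits, r, root_dist = c(0.5, 0.5)) {
  up <- .up_pass(tree, .tip_likelihoods(tree, traits), r, root_dist)
  tr <- up$tree
  ntip <- ape::Ntip(tr)
  ntot <- ntip + ape::Nnode(tr)
  down <- matrix(NA_real_, ntot, 2L)
  down[up$root, ] <- root_dist
  for (k in rev(seq_len(nrow(tr$edge)))) { # preorder
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    ## parent evidence excluding this child's subtree
    A <- down[p, ] * up$L[p, ] / up$msg[k, ]
    if (any(!is.finite(A))) { # msg hit exact zero: recompute sibling product
      sib <- which(tr$edge[, 1L] == p & seq_len(nrow(tr$edge)) != k)
      A <- down[p, ]
      for (s2 in sib) A <- A * up$msg[s2, ]
    }
    e <- exp(-2 * r * tr$edge.length[k])
    s <- 0.5 + 0.5 * e; w <- 0.5 - 0.5 * e
    down[ch, 1L] <- A[1L] * s + A[2L] * w
    down[ch, 2L] <- A[1L] * w + A[2L] * s
  }
  post <- up$L * down
  post <- post / rowSums(post)
  internal <- seq(ntip + 1L, ntot)
  probs <- post[internal, , drop = FALSE]
  dimnames(probs) <- list(internal, TRAIT_STATES)
  structure(list(probs = probs, rate = r, loglik = up$loglik,
                 tree = tr, method = "marginal"),
            class = "asr")
}

#' MCMC settings for the Bayesian binary reconstruction
#'
#' Defaults mirror a standard long production run: 5,000,000 generations,
#' four chains, sampling every 100 generations, 1000 sampled states
#' discarded as burn-in.
#'
#' @param n_generations,n_chains,sample_interval,burn_in_samples chain
#'   geometry.
#' @param seed RNG seed (chain `i` uses `seed + i - 1`).
#' @param proposal_scale standard deviation of the log-normal rate
#'   proposal.
#' @export
mcmc_settings <- function(n_generations = 5e6, n_chains = 4L,
                          sample_interval = 100L, burn_in_samples = 1000L,
                          seed = 1L, proposal_scale = 0.5) {
  stopifnot(n_generations > 0, n_chains > 0, sample_interval > 0,
            burn_in_samples >= 0, proposal_scale > 0)
  if (burn_in_samples >= n_generations / sample_interval)
    stop("burn_in_samples must be < n_generations / sample_interval")
  structure(list(n_generations = as.integer(n_generations),
                 n_chains = as.integer(n_chains),
                 sample_interval = as.integer(sample_interval),
                 burn_in_samples = as.integer(burn_in_samples),
                 seed = as.integer(seed),
                 proposal_scale = proposal_scale),
            class = "mcmc_settings")
}

## Draw a joint internal-state labelling from its conditional
## distribution given tips and rate, using the up-pass partials.
.sample_joint_states <- function(up, r, root_dist) {
  tr <- up$tree
  ntip <- ape::Ntip(tr)
  ntot <- ntip + ape::Nnode(tr)
  state <- integer(ntot)
  pr <- root_dist * up$L[up$root, ]
  state[up$root] <- 1L + (runif(1) >= pr[1L] / sum(pr))
  for (k in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    e <- exp(-2 * r * tr$edge.length[k])
    row <- c(0.5 + 0.5 * e, 0.5 - 0.5 * e)
    if (state[p] == 2L) row <- rev(row)
    pc <- row * up$L[ch, ]
    state[ch] <- 1L + (runif(1) >= pc[1L] / sum(pc))
  }
  state
}

#' Bayesian MCMC ancestral reconstruction of a binary trait
#'
#' Metropolis-Hastings over the log exchange rate (normal proposal on the
#' log scale, exponential(mean 1) prior on the rate); at each sampled
#' generation the internal states are drawn from their joint conditional
#' distribution given the tips and the current rate. Node posteriors are
#' post-burn-in state frequencies pooled across chains; per-chain
#' frequencies are kept for convergence checks.
#'
#' @inheritParams pruning_likelihood
#' @param settings an [mcmc_settings()] object.
#' @param fixed_rate if non-`NULL`, collapse the rate prior to this point
#'   mass (no rate updates).
#' @return object of class `asr` with pooled posterior matrix, per-chain
#'   matrices, and a rate posterior summary.
#' @export
bbm_mcmc <- function(tree, traits, settings = mcmc_settings(),
                     fixed_rate = NULL, root_dist = c(0.5, 0.5)) {
  stopifnot(inherits(settings, "mcmc_settings"))
  tipL <- .tip_likelihoods(tree, traits)
  tr0 <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr0)
  ntot <- ntip + ape::Nnode(tr0)
  n_samples <- settings$n_generations %/% settings$sample_interval
  keep <- seq(settings$burn_in_samples + 1L, n_samples)
  chain_counts <- vector("list", settings$n_chains)
  rate_samples <- vector("list", settings$n_chains)
  n_kept <- length(keep)
  for (chain in seq_len(settings$n_chains)) {
    set.seed(settings$seed + chain - 1L)
    if (is.null(fixed_rate)) {
      theta <- log(suppressWarnings(as.numeric(mle_rate(tree, traits, root_dist))))
      up <- .up_pass(tr0, tipL, exp(theta), root_dist)
      lp <- up$loglik - exp(theta) + theta # log-lik + log prior + Jacobian
    } else {
      theta <- log(fixed_rate)
      up <- .up_pass(tr0, tipL, fixed_rate, root_dist)
      lp <- 0
    }
    counts <- matrix(0L, ntot, 2L)
    rs <- numeric(0)
    drawn <- 0L
    for (g in seq_len(settings$n_generations)) {
      if (is.null(fixed_rate)) {
        theta_new <- theta + rnorm(1L, 0, settings$proposal_scale)
        up_new <- .up_pass(tr0, tipL, exp(theta_new), root_dist)
        lp_new <- up_new$loglik - exp(theta_new) + theta_new
        if (log(runif(1L)) < lp_new - lp) {
          theta <- theta_new; up <- up_new; lp <- lp_new
        }
      }
      if (g %% settings$sample_interval == 0L) {
        st <- .sample_joint_states(up, exp(theta), root_dist)
        drawn <- drawn + 1L
        if (drawn > settings$burn_in_samples) { # burn-in discarded here
          counts[cbind(seq_len(ntot), st)] <- counts[cbind(seq_len(ntot), st)] + 1L
          rs <- c(rs, exp(theta))
        }
      }
    }
    chain_counts[[chain]] <- counts
    rate_samples[[chain]] <- rs
  }
  pooled <- Reduce(`+`, chain_counts)
  internal <- seq(ntip + 1L, ntot)
  probs <- pooled[internal, , drop = FALSE] / (n_kept * settings$n_chains)
  dimnames(probs) <- list(internal, TRAIT_STATES)
  chain_probs <- lapply(chain_counts, function(m) {
    cp <- m[internal, , drop = FALSE] / n_kept
    dimnames(cp) <- list(internal, TRAIT_STATES)
    cp
  })
  rates <- unlist(rate_samples)
  structure(list(probs = probs, chain_probs = chain_probs,
                 rate = if (is.null(fixed_rate))
                   c(mean = mean(rates), median = median(rates),
                     lo95 = unname(quantile(rates, 0.025)),
                     hi95 = unname(quantile(rates, 0.975)))
                 else c(fixed = fixed_rate),
                 rate_samples = rate_samples,
                 n_samples_kept = n_kept, settings = settings,
                 tree = tr0, method = "bbm"),
            class = "asr")
}

#' @export
print.asr <- function(x, ...) {
  cat("Ancestral state reconstruction (", x$method, ")\n", sep = "")
  cat(" ", nrow(x$probs), "internal nodes;",
      ape::Ntip(x$tree), "tips\n")
  if (x$method == "marginal")
    cat("  rate =", signif(x$rate, 4),
        " log-likelihood =", signif(x$loglik, 6), "\n")
  else
    cat("  rate posterior:",
        paste(names(x$rate), signif(x$rate, 3), sep = "=", collapse = " "), "\n")
  rng <- range(x$probs[, 1L])
  cat("  P(", TRAIT_STATES[1L], ") across nodes: ",
      signif(rng[1L], 3), " - ", signif(rng[2L], 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.asr <- function(object, ...) {
  df <- data.frame(node = as.integer(rownames(object$probs)),
                   p_tolerant = object$probs[, 1L],
                   p_susceptible = object$probs[, 2L],
                   mode = TRAIT_STATES[max.col(object$probs, "first")],
                   row.names = NULL)
  df
}

#' Restrict a tree to the taxa with scored states
#'
#' Drops tips whose trait state is missing, suppressing the resulting
#' unary nodes and summing their branch lengths ([ape::keep.tip()]).
#'
#' @param tree `phylo`.
#' @param traits named state vector (`NA` = unscored).
#' @return pruned `phylo`.
#' @export
prune_to_scored <- function(tree, traits) {
  scored <- intersect(tree$tip.label, names(traits)[!is.na(traits)])
  if (length(scored) < 2L) stop("fewer than 2 scored taxa")
  ape::keep.tip(tree, scored)
}

#' Minimum transition and loss counts under parsimony
#'
#' Sankoff dynamic program with unit transition costs and a fixed root
#' state. Reports the minimum number of state changes, and among all
#' most-parsimonious labellings the minimum number of losses
#' (tolerant -> susceptible changes), with one witness labelling.
#'
#' @param tree `phylo`.
#' @param traits named binary states over the tips.
#' @param root_state state fixed at the root (default `"tolerant"`).
#' @return object of class `parsimony_losses`: `transitions`, `losses`,
#'   and a witness `states` vector over all nodes.
#' @export
count_losses <- function(tree, traits, root_state = "tolerant") {
  root_state <- match.arg(root_state, TRAIT_STATES)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  ntot <- ntip + ape::Nnode(tr)
  obs <- match(traits[tr$tip.label], TRAIT_STATES)
  if (any(is.na(obs))) stop("every tip needs a binary state")
  INF <- .Machine$integer.max %/% 4L
  Tc <- matrix(INF, ntot, 2L) # min transitions given node state
  Lc <- matrix(INF, ntot, 2L) # min losses among those
  Tc[cbind(seq_len(ntip), obs)] <- 0L
  Lc[cbind(seq_len(ntip), obs)] <- 0L
  choice <- array(NA_integer_, c(ntot, 2L, 2L)) # child state per (child-as-node, parent state)
  Tc[seq(ntip + 1L, ntot), ] <- 0L
  Lc[seq(ntip + 1L, ntot), ] <- 0L
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    for (s in 1:2) {
      best_t <- INF; best_l <- INF; best_x <- NA_integer_
      for (x in 1:2) {
        tt <- Tc[ch, x] + (s != x)
        ll <- Lc[ch, x] + (s == 1L && x == 2L)
        if (tt < best_t || (tt == best_t && ll < best_l)) {
          best_t <- tt; best_l <- ll; best_x <- x
        }
      }
      Tc[p, s] <- Tc[p, s] + best_t
      Lc[p, s] <- Lc[p, s] + best_l
      choice[ch, s, ] <- c(best_x, 0L)
    }
  }
  root <- tr$edge[nrow(tr$edge), 1L]
  rs <- match(root_state, TRAIT_STATES)
  states <- integer(ntot)
  states[root] <- rs
  for (k in rev(seq_len(nrow(tr$edge)))) { # preorder backtrack
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    states[ch] <- choice[ch, states[p], 1L]
  }
  labels <- TRAIT_STATES[states]
  names(labels) <- c(tr$tip.label, paste0("node", seq(ntip + 1L, ntot)))
  structure(list(transitions = Tc[root, rs], losses = Lc[root, rs],
                 states = labels, root_state = root_state, tree = tr),
            class = "parsimony_losses")
}

#' @export
print.parsimony_losses <- function(x, ...) {
  cat("Parsimony reconstruction (root fixed ", x$root_state, "):\n",
      "  minimum transitions: ", x$transitions, "\n",
      "  minimum losses (tolerant -> susceptible): ", x$losses, "\n",
      sep = "")
  invisible(x)
}
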