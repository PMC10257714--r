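## GCN-constrained null PCNs. A natural PCN is randomized while every edge
## stays inside the sample's GCN (expressed functions can only come from
## encoded genes):
##   null1 - uniform edge set of the same size, no degree constraint
##   null2 - taxon (row) degrees preserved
##   null3 - function (column) degrees preserved
##   null4 - both degree sequences preserved (restricted swap chain)

.null_variants <- c("null1", "null2", "null3", "null4")

#' Specification of a null-network randomization
#'
#' @param variant one of `"null1"`, `"null2"`, `"null3"`, `"null4"`.
#' @param nReplicates number of independent replicates (default 10).
#' @param seed integer seed; the replicate sequence is a pure function of
#'   the spec.
#' @param weightPolicy `"uniform"` assigns each taxon's new edges equal
#'   weight `1/degree`; `"permute"` redistributes the taxon's original
#'   weight multiset at random over its new edges (valid only when taxon
#'   degrees are preserved, i.e. null2/null4).
#' @return a `NullSpec` list with the derived degree-preservation flags.
#' @export
nullSpec <- function(variant = c("null1", "null2", "null3", "null4"),
                     nReplicates = 10L, seed = 1L,
                     weightPolicy = c("uniform", "permute")) {
  variant <- match.arg(variant)
  weightPolicy <- match.arg(weightPolicy)
  if (nReplicates < 1L) stop("nReplicates must be positive", call. = FALSE)
  preserveTaxon <- variant %in% c("null2", "null4")
  preserveFunction <- variant %in% c("null3", "null4")
  if (weightPolicy == "permute" && !preserveTaxon)
    stop("weightPolicy \"permute\" requires preserved taxon degrees ",
         "(null2 or null4)", call. = FALSE)
  structure(list(variant = variant,
                 preserve_taxon_degree = preserveTaxon,
                 preserve_function_degree = preserveFunction,
                 n_replicates = as.integer(nReplicates),
                 seed = as.integer(seed),
                 weight_policy = weightPolicy),
            class = "NullSpec")
}

## Restrict a PCN to the GCN background: edges absent from the GCN are
## dropped (annotation mismatches in real data); count reported via message.
.restrict_to_gcn <- function(pcn, gcn) {
  if (!all(taxa(pcn) %in% taxa(gcn)) ||
      !all(functionIds(pcn) %in% functionIds(gcn)))
    stop("PCN labels outside the GCN universe", call. = FALSE)
  wp <- networkWeights(pcn)
  bg <- networkWeights(gcn)[taxa(pcn), functionIds(pcn), drop = FALSE] > 0
  off <- wp > 0 & !bg
  if (any(off)) {
    message(sum(off), " PCN edge(s) absent from the GCN dropped before ",
            "randomization")
    wp[off] <- 0
    keep <- rowSums(wp) > 0
    wp <- wp[keep, , drop = FALSE]
  }
  TaxonFunctionNetwork(wp, "pcn", normalize = TRUE)
}

.sample_k <- function(x, k) x[sample.int(length(x), k)]

## One binary replicate in the PCN's index space (matrix of logicals).
.null_edges <- function(bp, bg, variant) {
  S <- nrow(bp); F_ <- ncol(bp)
  out <- matrix(FALSE, S, F_, dimnames = dimnames(bp))
  if (variant == "null1") {
    pool <- which(bg)
    out[.sample_k(pool, sum(bp))] <- TRUE
  } else if (variant == "null2") {
    for (i in seq_len(S)) {
      k <- sum(bp[i, ]); pool <- which(bg[i, ])
      if (k > length(pool))
        stop("infeasible: taxon ", rownames(bp)[i],
             " has PCN degree above its GCN degree", call. = FALSE)
      out[i, .sample_k(pool, k)] <- TRUE
    }
  } else if (variant == "null3") {
    for (a in seq_len(F_)) {
      k <- sum(bp[, a]); pool <- which(bg[, a])
      if (k > length(pool))
        stop("infeasible: function ", colnames(bp)[a],
             " has PCN degree above its GCN degree", call. = FALSE)
      out[.sample_k(pool, k), a] <- TRUE
    }
  } else {
    out <- .null4_chain(bp, bg, n_trades = 5L * sum(bp))
  }
  out
}

## Degree-preserving swap chain restricted to GCN-admissible cells: a trade
## moves function f from taxon u to v and g from v to u, accepted only when
## both destination cells are GCN edges. Row and column degrees are
## invariant under every accepted trade.
.null4_chain <- function(state, bg, n_trades) {
  S <- nrow(state)
  if (S < 2L) return(state)
  done <- 0L
  attempts <- 0L
  max_attempts <- max(200L * n_trades, 1000L)
  while (done < n_trades && attempts < max_attempts) {
    attempts <- attempts + 1L
    uv <- sample.int(S, 2L)
    u <- uv[1L]; v <- uv[2L]
    f_cand <- which(state[u, ] & !state[v, ] & bg[v, ])
    g_cand <- which(state[v, ] & !state[u, ] & bg[u, ])
    if (!length(f_cand) || !length(g_cand)) next
    f <- f_cand[sample.int(length(f_cand), 1L)]
    g <- g_cand[sample.int(length(g_cand), 1L)]
    state[u, f] <- FALSE; state[v, f] <- TRUE
    state[v, g] <- FALSE; state[u, g] <- TRUE
    done <- done + 1L
  }
  state
}

.apply_weights <- function(edges, pcn, policy) {
  w <- matrix(0, nrow(edges), ncol(edges), dimnames = dimnames(edges))
  wp <- networkWeights(pcn)
  for (i in seq_len(nrow(edges))) {
    idx <- which(edges[i, ])
    if (!length(idx)) next
    if (policy == "uniform") {
      w[i, idx] <- 1 / length(idx)
    } else {
      orig <- wp[i, wp[i, ] > 0]
      w[i, idx] <- sample(orig)
    }
  }
  TaxonFunctionNetwork(w, "pcn", normalize = TRUE)
}

#' Generate GCN-constrained null PCNs
#'
#' Draws `spec$n_replicates` random networks whose edges are all GCN edges,
#' with the degree constraints implied by the variant (see [nullSpec()]).
#' Edge count equals the (GCN-restricted) PCN's edge count; for null2/null4
#' every taxon keeps its PCN degree, for null3/null4 every function keeps
#' its PCN degree. The replicate sequence is deterministic in `spec$seed`.
#'
#' @param pcn,gcn [TaxonFunctionNetwork-class] objects; PCN labels must lie
#'   inside the GCN universe. PCN edges missing from the GCN are dropped
#'   (with a message) before randomization.
#' @param spec a [nullSpec()].
#' @return list of [TaxonFunctionNetwork-class] replicates.
#' @export
randomizeNetwork <- function(pcn, gcn, spec) {
  stopifnot(inherits(spec, "NullSpec"))
  pcn <- .restrict_to_gcn(pcn, gcn)
  bp <- networkWeights(pcn) > 0
  bg <- networkWeights(gcn)[taxa(pcn), functionIds(pcn), drop = FALSE] > 0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_replicates), function(r) {
    e <- .null_edges(bp, bg, spec$variant)
    .apply_weights(e, pcn, spec$weight_policy)
  })
}

#' Diversity and topology metrics across null replicates
#'
#' Recomputes TD/FD/FR/nFR and NODF for the natural PCN and for each
#' replicate of the requested null variants, using the same biomass profile
#' throughout. The natural network appears as variant `"natural"`,
#' replicate 0.
#'
#' @inheritParams randomizeNetwork
#' @param profile an [AbundanceProfile-class] for the sample.
#' @param variants character vector among `"null1"..."null4"`, default all.
#' @param nReplicates,seed,weightPolicy forwarded to [nullSpec()]
#'   (replicates default to 10).
#' @return data.frame: variant, replicate, td, fd, fr, nfr, nodf.
#' @export
nullFRComparison <- function(pcn, gcn, profile, variants = .null_variants,
                             nReplicates = 10L, seed = 1L,
                             weightPolicy = "uniform") {
  variants <- match.arg(variants, .null_variants, several.ok = TRUE)
  one_row <- function(net, variant, rep) {
    s <- sampleSummary(net, profile)
    nd <- tryCatch(nodf(net)$nodf, error = function(e) NA_real_)
    data.frame(variant = variant, replicate = rep, td = td(s), fd = fd(s),
               fr = fr(s), nfr = nfr(s), nodf = nd, stringsAsFactors = FALSE)
  }
  out <- list(one_row(pcn, "natural", 0L))
  for (v in variants) {
    sp <- nullSpec(v, nReplicates = nReplicates, seed = seed,
                   weightPolicy = weightPolicy)
    reps <- randomizeNetwork(pcn, gcn, sp)
    for (r in seq_along(reps))
      out[[length(out) + 1L]] <- one_row(reps[[r]], v, r)
  }
  do.call(rbind, out)
}
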