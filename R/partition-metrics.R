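#' Contingency table between ground truth and prediction
#'
#' Cross-tabulates class labels against predicted clusters. All
#' pair-counting machinery (the number of object pairs N, the same-class
#' pair count P, the same-cluster pair count Q, and their per-class /
#' per-cluster decompositions) derives from this table via
#' \code{\link{pairCounts}}.
#'
#' @param labels a \linkS4class{LabelVector}.
#' @param partition a \linkS4class{Partition} aligned to \code{labels}.
#' @return a \linkS4class{Contingency}.
#' @export
contingencyTable <- function(labels, partition) {
    .checkAligned(labels, partition)
    if (nCells(labels) < 2L) stop("need at least 2 cells (no object pairs)")
    tab <- table(class = groups(labels), cluster = groups(partition))
    new("Contingency", table = unclass(matrix(as.numeric(tab), nrow(tab),
                                              ncol(tab),
                                              dimnames = dimnames(tab))))
}

#' Pair-counting quantities of a contingency table
#'
#' @param x a \linkS4class{Contingency}.
#' @return a list with \code{n} (cells), \code{N = n(n-1)/2} (object pairs),
#'   \code{Pi}, \code{Qj} (per-class and per-cluster same-group pair counts
#'   \eqn{\binom{n_{i+}}{2}}, \eqn{\binom{n_{+j}}{2}}), their totals
#'   \code{P}, \code{Q}, the joint pair count \code{sumCij}
#'   (\eqn{\sum_{ij}\binom{n_{ij}}{2}}) with row/column partial sums, and
#'   the proportion vectors \code{pij}, \code{pi}, \code{pj}.
#' @export
pairCounts <- function(x) {
    tab <- x@table
    n <- sum(tab)
    rs <- rowSums(tab); cs <- colSums(tab)
    list(n = n, N = choose(n, 2),
         Pi = choose(rs, 2), Qj = choose(cs, 2),
         P = sum(choose(rs, 2)), Q = sum(choose(cs, 2)),
         sumCij = sum(choose(tab, 2)),
         rowCij = rowSums(choose(tab, 2)),
         colCij = colSums(choose(tab, 2)),
         pij = tab / n, pi = rs / n, pj = cs / n)
}

#' Chance-adjusted Wallace indices with decompositions
#'
#' The Wallace index W is the proportion of same-class object pairs that are
#' also placed in the same cluster; V is its converse. Both are adjusted for
#' chance as \eqn{(S - E(S)) / (1 - E(S))} with the expectation taken under
#' the generalized hypergeometric model of random partitions with fixed
#' margins, giving
#' \deqn{AW = \frac{N\sum_{ij}\binom{n_{ij}}{2} - PQ}{P(N-Q)}, \qquad
#'       AV = \frac{N\sum_{ij}\binom{n_{ij}}{2} - PQ}{Q(N-P)}.}
#' AW measures the completeness of classes (0 at chance, 1 perfect), AV the
#' homogeneity of clusters. Both decompose into one value per class
#' (\eqn{AW_i}) and per cluster (\eqn{AV_j}); components whose denominator
#' vanishes (singleton classes/clusters, or a trivial counterpart partition)
#' are returned as \code{NA} ("undefined") rather than raising an error.
#'
#' @param x a \linkS4class{Contingency}.
#' @return a list with scalars \code{AW}, \code{AV} and named vectors
#'   \code{AWi} (per class), \code{AVj} (per cluster); undefined entries are
#'   \code{NA}.
#' @export
wallaceAdjusted <- function(x) {
    pc <- pairCounts(x)
    Tnum <- pc$N * pc$sumCij - pc$P * pc$Q
    AW <- if (pc$P > 0 && pc$N > pc$Q) Tnum / (pc$P * (pc$N - pc$Q)) else NA_real_
    AV <- if (pc$Q > 0 && pc$N > pc$P) Tnum / (pc$Q * (pc$N - pc$P)) else NA_real_
    AWi <- ifelse(pc$Pi > 0 & pc$N > pc$Q,
                  (pc$N * pc$rowCij - pc$Pi * pc$Q) / (pc$Pi * (pc$N - pc$Q)),
                  NA_real_)
    AVj <- ifelse(pc$Qj > 0 & pc$N > pc$P,
                  (pc$N * pc$colCij - pc$Qj * pc$P) / (pc$Qj * (pc$N - pc$P)),
                  NA_real_)
    names(AWi) <- rownames(x@table)
    names(AVj) <- colnames(x@table)
    list(AW = AW, AV = AV, AWi = AWi, AVj = AVj)
}

#' Adjusted Rand index, by two routes
#'
#' The adjusted Rand index is the harmonic mean of the adjusted Wallace
#' indices AW and AV, summarizing class completeness and cluster homogeneity
#' at once. It equally admits an exact decomposition as a weighted average
#' of the per-class \eqn{AW_i} and per-cluster \eqn{AV_j}, with weights
#' \eqn{P_i(N-Q)} and \eqn{Q_j(N-P)} respectively (these weights — not the
#' bare pair counts \eqn{P_i}, \eqn{Q_j} — make the decomposition agree with
#' the harmonic mean identically; see the package vignette). Both routes are
#' returned and agree to machine precision whenever defined; large classes
#' dominate the weights, which motivates the debiased variant
#' \code{\link{ari2}}.
#'
#' @param x a \linkS4class{Contingency}.
#' @return a list with \code{ARI} (the index), \code{harmonic} and
#'   \code{decomposed} (the two computation routes).
#' @export
ari <- function(x) {
    pc <- pairCounts(x)
    w <- wallaceAdjusted(x)
    num <- pc$sumCij - pc$P * pc$Q / pc$N
    den <- (pc$P + pc$Q) / 2 - pc$P * pc$Q / pc$N
    ARI <- if (den != 0) num / den else NA_real_
    harmonic <- if (!is.na(w$AW) && !is.na(w$AV)) {
        if (w$AW == w$AV) w$AW else 2 * w$AW * w$AV / (w$AW + w$AV)
    } else NA_real_
    wi <- pc$Pi * (pc$N - pc$Q)
    vj <- pc$Qj * (pc$N - pc$P)
    defI <- !is.na(w$AWi); defJ <- !is.na(w$AVj)
    wSum <- sum(wi[defI]) + sum(vj[defJ])
    decomposed <- if (wSum > 0)
        (sum(w$AWi[defI] * wi[defI]) + sum(w$AVj[defJ] * vj[defJ])) / wSum
    else NA_real_
    list(ARI = ARI, harmonic = harmonic, decomposed = decomposed)
}

#' Class-size-debiased adjusted Rand index (ARI2)
#'
#' The weighted decomposition underlying ARI lets large classes dominate,
#' yet rare cell types are often the analytes of interest. ARI2 replaces the
#' weighted averages by unweighted means of the per-class and per-cluster
#' components, \eqn{AW' = \mathrm{mean}_i\, AW_i} and
#' \eqn{AV' = \mathrm{mean}_j\, AV_j}, and combines them as their harmonic
#' mean \eqn{2\,AW'AV' / (AW' + AV')}. Undefined components (singleton
#' classes or clusters, whose adjusted index is 0/0) are excluded from the
#' means with a warning.
#'
#' @param x a \linkS4class{Contingency}.
#' @return a list with \code{ARI2}, \code{AWprime}, \code{AVprime}
#'   (\code{NA} when undefined).
#' @export
ari2 <- function(x) {
    w <- wallaceAdjusted(x)
    nUndef <- sum(is.na(w$AWi)) + sum(is.na(w$AVj))
    if (nUndef > 0)
        warning(sprintf(
            "%d undefined per-group component(s) (singleton groups) excluded from ARI2",
            nUndef))
    AWp <- .meanDefined(w$AWi)
    AVp <- .meanDefined(w$AVj)
    ARI2 <- if (is.na(AWp) || is.na(AVp) || (AWp + AVp) == 0) {
        if (!is.na(AWp) && !is.na(AVp) && AWp == 0 && AVp == 0) 0
        else NA_real_
    } else if (AWp == AVp) AWp else 2 * AWp * AVp / (AWp + AVp)
    list(ARI2 = ARI2, AWprime = AWp, AVprime = AVp)
}

#' Mutual information and variation of information
#'
#' Information-theoretic agreement between two partitions, in nats. MI is
#' computed from the joint proportions,
#' \eqn{\mathrm{MI} = \sum_{ij} p_{ij}\log\frac{p_{ij}}{p_i p_j}}, and
#' satisfies \eqn{\mathrm{MI} = H(Z) - H(Z|U)}; VI is the conditional-entropy
#' sum \eqn{H(U|Z) + H(Z|U)}, equivalently \eqn{H(U) + H(Z) - 2\,\mathrm{MI}}.
#' The convention \eqn{0\log 0 = 0} applies throughout. MI is a homogeneity
#' measure (larger is better, unnormalized); VI is a distance (0 for
#' identical partitions).
#'
#' @param x a \linkS4class{Contingency}.
#' @return a list with \code{MI}, \code{VI}, \code{HU}, \code{HZ},
#'   \code{HUgivenZ}, \code{HZgivenU}.
#' @export
miVi <- function(x) {
    pc <- pairCounts(x)
    xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
    HU <- -sum(xlogx(pc$pi))
    HZ <- -sum(xlogx(pc$pj))
    Hjoint <- -sum(xlogx(pc$pij))
    pos <- pc$pij > 0
    outer_pipj <- outer(pc$pi, pc$pj)
    MI <- sum(pc$pij[pos] * log(pc$pij[pos] / outer_pipj[pos]))
    HUgivenZ <- Hjoint - HZ
    HZgivenU <- Hjoint - HU
    VI <- HUgivenZ + HZgivenU
    list(MI = MI, VI = VI, HU = HU, HZ = HZ,
         HUgivenZ = HUgivenZ, HZgivenU = HZgivenU)
}

#' Evenness of a labelled dataset
#'
#' \eqn{E = \exp(H(U)) / K}, the exponential Shannon entropy (effective
#' number of classes) of the class proportions relative to the actual number
#' of classes K. Ranges from 1/K (one class dominates completely) to 1
#' (perfectly balanced).
#'
#' @param labels a \linkS4class{LabelVector}.
#' @return a numeric scalar in (0, 1].
#' @export
evenness <- function(labels) {
    p <- as.numeric(table(groups(labels))) / nCells(labels)
    p <- p[p > 0]
    H <- -sum(p * log(p))
    exp(H) / nGroups(labels)
}

#' All partition-level scores at once
#'
#' Convenience wrapper computing the adjusted Wallace indices and their
#' decompositions, ARI, ARI2, MI, VI and the evenness of the ground truth
#' from one aligned (labels, partition) pair.
#'
#' @param labels a \linkS4class{LabelVector}.
#' @param partition a \linkS4class{Partition} aligned to \code{labels}.
#' @return a list with \code{scores} (named numeric: AW, AV, ARI, ARI2,
#'   AWprime, AVprime, MI, VI, evenness), \code{AWi}, \code{AVj}, and the
#'   \code{contingency} object.
#' @examples
#' u <- LabelVector(letters[1:6], c("T", "T", "T", "B", "B", "NK"))
#' z <- Partition(letters[1:6], c(1, 1, 2, 2, 2, 3))
#' partitionScores(u, z)$scores
#' @export
partitionScores <- function(labels, partition) {
    ct <- contingencyTable(labels, partition)
    w <- wallaceAdjusted(ct)
    a <- ari(ct)
    a2 <- suppressWarnings(ari2(ct))
    mv <- miVi(ct)
    list(scores = c(AW = w$AW, AV = w$AV, ARI = a$ARI, ARI2 = a2$ARI2,
                    AWprime = a2$AWprime, AVprime = a2$AVprime,
                    MI = mv$MI, VI = mv$VI, evenness = evenness(labels)),
         AWi = w$AWi, AVj = w$AVj, contingency = ct)
}
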