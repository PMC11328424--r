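#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' Alignment error for paired cross-modality embeddings. With
#' \eqn{d_{i,j}} the cosine distance between row \eqn{i} of \eqn{X_1} and
#' row \eqn{j} of \eqn{X_2}, cell \eqn{i}'s score is
#' \eqn{\mathrm{frac}_i = (R_i - 1)/(n - 1)} where \eqn{R_i} counts the
#' cells \eqn{j} with \eqn{d_{i,j} \le d_{i,i}} — ties count against the
#' match, the conservative convention. The score is recomputed with the two
#' modalities swapped and the two directions averaged per cell. 0 means
#' every cell is closest to its own match; 0.5 is the chance level of
#' unrelated embeddings.
#'
#' @param pair a \linkS4class{PairedEmbeddings}.
#' @return a list with \code{perCell} (numeric in [0, 1]) and \code{mean}.
#' @examples
#' sim <- simulatePaired(simConfig(nCells = 100, seed = 7,
#'                                 noiseSigmaModality2 = 0.1))
#' foscttm(sim$pair)$mean
#' @export
foscttm <- function(pair) {
    X1 <- pair@X1; X2 <- pair@X2
    n <- nrow(X1)
    X1 <- X1 / sqrt(rowSums(X1^2))
    X2 <- X2 / sqrt(rowSums(X2^2))
    D <- 1 - tcrossprod(X1, X2)            # d[i, j] = cosine dist X1_i, X2_j
    dTrue <- diag(D)
    R1 <- rowSums(D <= dTrue)              # direction X1 -> X2
    R2 <- colSums(D <= rep(dTrue, each = n))  # swapped roles: d'_{i,j} = D[j, i]
    frac1 <- (R1 - 1) / (n - 1)
    frac2 <- (R2 - 1) / (n - 1)
    perCell <- (frac1 + frac2) / 2
    names(perCell) <- rownames(pair@X1)
    list(perCell = perCell, mean = mean(perCell))
}
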