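#' SimConfig: parameters of the synthetic-data generator
#'
#' Describes a Gaussian-mixture embedding with controllable class
#' separation, class-size imbalance (including rare classes), optional
#' nested class structure, log-normal library sizes with an optional loading
#' onto the first latent dimension, and a paired second modality related by
#' additive noise.
#'
#' @slot nCells total cells.
#' @slot classProportions simplex vector of class proportions.
#' @slot nDims latent dimensions.
#' @slot separation expected between-class mean distance in units of the
#'   within-class standard deviation (isotropic, unit within-class s.d.).
#' @slot hierarchy optional list; each element is
#'   \code{list(parent = <class index>, offsets = <matrix>)} splitting that
#'   class into subclasses displaced by the offset rows.
#' @slot libsizeMu,libsizeSigma log-normal parameters of library size
#'   (meanlog, sdlog).
#' @slot biasLoading coefficient of \code{sqrt(library size)} added to
#'   latent dimension 1 (0 = no technical leakage).
#' @slot noiseSigmaModality2 s.d. of the additive Gaussian noise relating
#'   the paired modality to the first.
#' @slot seed integer seed; all randomness flows through one seeded
#'   generator per call and the caller's RNG state is untouched.
#' @export
setClass("SimConfig",
         slots = c(nCells = "numeric", classProportions = "numeric",
                   nDims = "numeric", separation = "numeric",
                   hierarchy = "list",
                   libsizeMu = "numeric", libsizeSigma = "numeric",
                   biasLoading = "numeric", noiseSigmaModality2 = "numeric",
                   seed = "numeric"))

setValidity("SimConfig", function(object) {
    if (object@nCells < 2) return("nCells must be >= 2")
    p <- object@classProportions
    if (any(p <= 0) || abs(sum(p) - 1) > 1e-8)
        return("classProportions must be positive and sum to 1")
    if (object@nDims < 1) return("nDims must be >= 1")
    if (object@separation < 0 || object@libsizeSigma < 0 ||
        object@noiseSigmaModality2 < 0)
        return("scale parameters must be >= 0")
    TRUE
})

#' @param nCells,classProportions,nDims,separation,hierarchy,libsizeMu,libsizeSigma,biasLoading,noiseSigmaModality2,seed
#'   see the slot documentation. The defaults (2000 cells, class proportions
#'   0.4/0.3/0.2/0.1 including a rare class, 15 dimensions, separation 8,
#'   median library size ~10,000 fragments with sdlog 0.5) emulate a
#'   moderately easy single-cell task.
#' @rdname SimConfig-class
#' @export
simConfig <- function(nCells = 2000,
                      classProportions = c(0.4, 0.3, 0.2, 0.1),
                      nDims = 15, separation = 8, hierarchy = list(),
                      libsizeMu = log(10000), libsizeSigma = 0.5,
                      biasLoading = 0, noiseSigmaModality2 = 1,
                      seed = 42) {
    new("SimConfig", nCells = nCells, classProportions = classProportions,
        nDims = nDims, separation = separation, hierarchy = hierarchy,
        libsizeMu = libsizeMu, libsizeSigma = libsizeSigma,
        biasLoading = biasLoading,
        noiseSigmaModality2 = noiseSigmaModality2, seed = seed)
}

# Class means at pairwise distance `separation`: scaled standard-basis
# vectors (a regular simplex with the requested edge length), centered and
# randomly rotated. Needs K <= d; otherwise means are drawn isotropic
# Gaussian with E||mu_a - mu_b||^2 matching separation^2 instead.
.classMeans <- function(K, d, separation) {
    if (K <= d) {
        mu <- matrix(0, K, d)
        mu[cbind(seq_len(K), seq_len(K))] <- separation / sqrt(2)
        mu <- sweep(mu, 2L, colMeans(mu))
        Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
        mu %*% Q
    } else {
        matrix(stats::rnorm(K * d, sd = separation / sqrt(2 * d)), K, d)
    }
}

# largest-remainder rounding of proportions to integer class sizes
.classSizes <- function(n, p) {
    raw <- n * p
    sizes <- floor(raw)
    rem <- n - sum(sizes)
    if (rem > 0) {
        o <- order(raw - sizes, decreasing = TRUE)
        sizes[o[seq_len(rem)]] <- sizes[o[seq_len(rem)]] + 1
    }
    if (any(sizes == 0))
        stop("a class received 0 cells after rounding; increase nCells")
    sizes
}

#' Simulate a labelled embedding with library sizes
#'
#' Class means sit on a randomly rotated regular simplex with edge length
#' \code{separation} (so every pair of classes is exactly \code{separation}
#' apart; when K exceeds d + 1 the means are instead drawn isotropic
#' Gaussian with matching expected distance); cells are the class mean plus
#' isotropic unit Gaussian noise, so \code{separation} is the difficulty
#' axis in units of the within-class standard deviation (0 = labels carry
#' no spatial signal; 50 = classes essentially disjoint). Library sizes are log-normal (rounded up to at
#' least 1 fragment); when \code{biasLoading > 0}, dimension 1 additionally
#' receives \code{biasLoading * sqrt(library size)}, emulating the depth
#' leakage of LSI-style embeddings. With a \code{hierarchy}, affected
#' classes are split into subclasses displaced by the given offsets, and the
#' returned labels name the subclasses (\code{"<parent>.<part>"}).
#'
#' Output is bit-reproducible from \code{config@seed}; the caller's RNG
#' state is left untouched.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a list with \code{embedding} (\linkS4class{EmbeddingMatrix}),
#'   \code{labels} (\linkS4class{LabelVector}) and \code{libsize}
#'   (\linkS4class{LibrarySizeVector}), all aligned.
#' @export
simulateEmbedding <- function(config) {
    stopifnot(is(config, "SimConfig"))
    .withSeed(config@seed, {
        K <- length(config@classProportions)
        d <- config@nDims
        n <- config@nCells
        sizes <- .classSizes(n, config@classProportions)
        mu <- .classMeans(K, d, config@separation)
        classIdx <- rep(seq_len(K), sizes)
        labels <- sprintf("class%d", classIdx)
        means <- mu[classIdx, , drop = FALSE]
        if (length(config@hierarchy)) {
            for (h in config@hierarchy) {
                sel <- which(classIdx == h$parent)
                off <- as.matrix(h$offsets)
                part <- rep_len(seq_len(nrow(off)), length(sel))
                means[sel, ] <- means[sel, , drop = FALSE] +
                    off[part, , drop = FALSE]
                labels[sel] <- sprintf("%s.%d", labels[sel], part)
            }
        }
        co <- means + matrix(stats::rnorm(n * d), n, d)
        counts <- pmax(1, round(stats::rlnorm(n, config@libsizeMu,
                                              config@libsizeSigma)))
        if (config@biasLoading > 0)
            co[, 1] <- co[, 1] + config@biasLoading * sqrt(counts)
        ids <- sprintf("cell%0*d", nchar(n), seq_len(n))
        list(embedding = EmbeddingMatrix(co, cellIds = ids),
             labels = LabelVector(ids, labels),
             libsize = LibrarySizeVector(ids, counts))
    })
}

#' Perturb a ground-truth labelling into a predicted partition
#'
#' Generates the canonical failure modes of clustering against a known
#' truth: \code{merge} joins named classes into one cluster
#' (under-clustering), \code{split} divides one class uniformly at random
#' into a given number of parts (over-clustering; parts are guaranteed
#' non-empty, so the cluster count rises by exactly \code{parts - 1}), and
#' \code{relabel} reassigns \code{ceiling(fraction * n)} random cells to
#' uniform random clusters (noise).
#'
#' @param labels a \linkS4class{LabelVector}.
#' @param action \code{"merge"}, \code{"split"} or \code{"relabel"}.
#' @param classes for \code{merge}: names of >= 2 classes to join.
#' @param class,parts for \code{split}: the class name and the number of
#'   parts (\code{parts <= } class size).
#' @param fraction for \code{relabel}: fraction of cells in [0, 1] to
#'   reassign.
#' @param seed integer seed (private generator; global RNG untouched).
#' @return a \linkS4class{Partition} over the same cells.
#' @export
perturbPartition <- function(labels, action = c("merge", "split", "relabel"),
                             classes = NULL, class = NULL, parts = 2,
                             fraction = 0, seed = 1) {
    action <- match.arg(action)
    g <- as.character(groups(labels))
    .withSeed(seed, {
        if (action == "merge") {
            if (length(classes) < 2L) stop("merge needs >= 2 classes")
            if (!all(classes %in% g)) stop("unknown class in `classes`")
            g[g %in% classes] <- paste(classes, collapse = "+")
        } else if (action == "split") {
            sel <- which(g == class)
            if (!length(sel)) stop("unknown class")
            if (parts > length(sel))
                stop("cannot split a class into more parts than cells")
            part <- sample(rep_len(seq_len(parts), length(sel)))
            g[sel] <- sprintf("%s.%d", class, part)
        } else {
            if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
            nMove <- ceiling(fraction * length(g))
            if (nMove > 0) {
                targets <- unique(g)
                move <- sample(length(g), nMove)
                g[move] <- sample(targets, nMove, replace = TRUE)
            }
        }
        Partition(cellIds(labels), g)
    })
}

#' Simulate paired cross-modality embeddings
#'
#' The first modality comes from \code{\link{simulateEmbedding}}; the second
#' is the first plus isotropic Gaussian noise with s.d.
#' \code{noiseSigmaModality2}. Noise 0 gives FOSCTTM 0; as the noise grows
#' the modalities decouple and FOSCTTM approaches the chance level 0.5.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a list with \code{pair} (\linkS4class{PairedEmbeddings}),
#'   \code{labels} and \code{libsize}.
#' @export
simulatePaired <- function(config) {
    sim <- simulateEmbedding(config)
    X1 <- coords(sim$embedding)
    noise <- .withSeed(config@seed + 1L,
        matrix(stats::rnorm(length(X1), sd = config@noiseSigmaModality2),
               nrow(X1), ncol(X1)))
    X2 <- X1 + noise
    list(pair = PairedEmbeddings(X1, X2, cellIds = rownames(X1)),
         labels = sim$labels, libsize = sim$libsize)
}
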