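# Independent brute-force oracles. These deliberately use the dumbest
# possible algorithms (all-pairs loops, explicit run scanning, direct
# eigendecomposition) so that they share no code path with the package.

oracleColStats <- function(x) {
    mu <- numeric(nrow(x)); sdv <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
        mu[i] <- sum(x[i, ]) / ncol(x)
        sdv[i] <- sqrt(sum((x[i, ] - mu[i])^2) / (ncol(x) - 1))
    }
    list(mean = mu, sd = sdv)
}

# run scanner over marker indices, one individual/chromosome at a time
oracleSegments <- function(calls, map, minMarkers = 3, maxGapMarkers = 0) {
    out <- NULL
    for (id in unique(calls$individual)) {
        for (ch in unique(calls$chrom[calls$individual == id])) {
            d <- calls[calls$individual == id & calls$chrom == ch, ]
            idx <- match(d$marker, names(map))
            o <- order(idx); idx <- idx[o]; d <- d[o, ]
            runStart <- 1
            flush <- function(a, b) {
                n <- b - a + 1
                if (n < minMarkers) return(NULL)
                st <- unique(d$state[a:b])
                data.frame(individual = id, chrom = ch,
                           start = d$pos[a], end = d$pos[b], nMarkers = n,
                           state = if (length(st) == 1) st else "mixed")
            }
            if (nrow(d) >= 1) {
                for (i in seq_len(nrow(d))[-1]) {
                    if (idx[i] - idx[i - 1] > maxGapMarkers + 1) {
                        out <- rbind(out, flush(runStart, i - 1))
                        runStart <- i
                    }
                }
                out <- rbind(out, flush(runStart, nrow(d)))
            }
        }
    }
    if (is.null(out)) return(out)
    out[order(out$individual, out$chrom, out$start), ]
}

# union-find over all segment pairs; overlap means sharing >= 1 bp
oracleMergeCnvrs <- function(seg) {
    n <- nrow(seg)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i < j && seg$chrom[i] == seg$chrom[j] &&
            seg$start[i] <= seg$end[j] && seg$start[j] <= seg$end[i]) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
        }
    }
    root <- vapply(seq_len(n), find, integer(1))
    out <- NULL
    for (r in unique(root)) {
        m <- seg[root == r, ]
        st <- unique(m$state)
        state <- if (identical(st, "gain")) "gain"
                 else if (identical(st, "loss")) "loss" else "both"
        out <- rbind(out, data.frame(chrom = m$chrom[1], start = min(m$start),
                                     end = max(m$end), state = state,
                                     nSegments = nrow(m)))
    }
    out[order(out$chrom, out$start), ]
}

oracleIntersect <- function(a, b) {
    out <- NULL
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        if (a$chrom[i] != b$chrom[j]) next
        lo <- max(a$start[i], b$start[j]); hi <- min(a$end[i], b$end[j])
        if (hi >= lo)
            out <- rbind(out, data.frame(i = i, j = j, overlap = hi - lo + 1))
    }
    out
}

oraclePositionFrequency <- function(calls, labels, groupBy, minFraction) {
    grp <- labels[[groupBy]]
    out <- NULL
    for (g in unique(grp)) {
        ids <- labels$individual[grp == g]
        d <- calls[calls$individual %in% ids, ]
        if (!nrow(d)) next
        key <- unique(d[, c("chrom", "pos", "state")])
        for (k in seq_len(nrow(key))) {
            carr <- unique(d$individual[d$chrom == key$chrom[k] &
                                        d$pos == key$pos[k] &
                                        d$state == key$state[k]])
            out <- rbind(out, data.frame(
                group = g, chrom = key$chrom[k], pos = key$pos[k],
                state = key$state[k], nCarriers = length(carr),
                fraction = length(carr) / length(ids),
                retained = length(carr) / length(ids) >= minFraction))
        }
    }
    out[order(out$group, out$chrom, out$pos, out$state), ]
}

# exhaustive set logic: private iff the (pos, state) carrier set lives in one group
oracleUniquePrivate <- function(freq) {
    key <- function(d) paste(d$chrom, d$pos, d$state)
    priv <- logical(nrow(freq))
    for (i in seq_len(nrow(freq))) {
        others <- freq[freq$group != freq$group[i], ]
        priv[i] <- !key(freq[i, ]) %in% key(others)
    }
    priv
}

oraclePca <- function(x, center = TRUE, scale = FALSE) {
    if (center) x <- sweep(x, 2, colMeans(x))
    if (scale) x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
    ev <- eigen(stats::cov(x), symmetric = TRUE)
    scores <- x %*% ev$vectors
    for (j in seq_len(ncol(scores))) {
        i <- which.max(abs(ev$vectors[, j]))
        if (ev$vectors[i, j] < 0) {
            ev$vectors[, j] <- -ev$vectors[, j]
            scores[, j] <- -scores[, j]
        }
    }
    list(scores = scores, loadings = ev$vectors,
         varianceExplained = ev$values / sum(ev$values))
}

oracleUnionLength <- function(start, end) {
    if (!length(start)) return(0)
    o <- order(start)
    start <- start[o]; end <- end[o]
    tot <- 0; curS <- start[1]; curE <- end[1]
    for (i in seq_along(start)[-1]) {
        if (start[i] <= curE + 0) curE <- max(curE, end[i])
        else { tot <- tot + curE - curS + 1; curS <- start[i]; curE <- end[i] }
    }
    tot + curE - curS + 1
}

# exact mean silhouette on a score matrix with cluster labels
oracleSilhouette <- function(x, labels) {
    d <- as.matrix(stats::dist(x))
    n <- nrow(d)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- labels == labels[i]; own[i] <- FALSE
        if (!any(own)) { s[i] <- 0; next }
        a <- mean(d[i, own])
        b <- min(vapply(setdiff(unique(labels), labels[i]),
                        function(g) mean(d[i, labels == g]), numeric(1)))
        s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    mean(s)
}
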