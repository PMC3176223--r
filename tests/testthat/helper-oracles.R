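# Independent oracles used across the suite. These deliberately avoid the
# package's own kernels: labelling by plain flood fill, Euler
# characteristic by quad counting, the Hamiltonian by exhaustive pair
# enumeration.

# Flood-fill component labelling (pure R, stack of linear indices).
floodLabelOracle <- function(mask, conn = 8) {
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(0L, nr, nc)
    dr <- if (conn == 8) c(1, -1, 0, 0, 1, 1, -1, -1) else c(1, -1, 0, 0)
    dc <- if (conn == 8) c(0, 0, 1, -1, 1, -1, 1, -1) else c(0, 0, 1, -1)
    nxt <- 0L
    for (start in which(mask != 0)) {
        if (lab[start] != 0) next
        nxt <- nxt + 1L
        stack <- start
        lab[start] <- nxt
        while (length(stack)) {
            p <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pr <- (p - 1L) %% nr + 1L
            pc <- (p - 1L) %/% nr + 1L
            for (k in seq_along(dr)) {
                r <- pr + dr[k]; c2 <- pc + dc[k]
                if (r >= 1 && r <= nr && c2 >= 1 && c2 <= nc &&
                    mask[r, c2] != 0 && lab[r, c2] == 0) {
                    q <- (c2 - 1L) * nr + r
                    lab[q] <- nxt
                    stack <- c(stack, q)
                }
            }
        }
    }
    lab
}

# Euler characteristic (8-connectivity foreground) via Gray's quad counts
# on the zero-padded image: chi8 = (Q1 - Q3 - 2*Qd)/4 = beta0 - beta1.
eulerQuadOracle <- function(mask) {
    m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
    m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
    a <- m[-nrow(m), -ncol(m)]
    b <- m[-nrow(m), -1]
    c2 <- m[-1, -ncol(m)]
    d <- m[-1, -1]
    s <- a + b + c2 + d
    q1 <- sum(s == 1)
    q3 <- sum(s == 3)
    qd <- sum(s == 2 & ((a == 1 & d == 1) | (b == 1 & c2 == 1)))
    (q1 - q3 - 2 * qd) / 4
}

# Exhaustive Hamiltonian: every unordered neighbor pair once; sites beyond
# the lattice edge count as medium and are owned by the interior member.
bruteHamiltonian <- function(state, params) {
    sig <- state@sigma
    L <- nrow(sig)
    offs <- vasculogen:::cpm_neighborhood(params@neighborOrder)
    Jof <- function(a, b) {
        if (a == b) return(0)
        if (a > 0 && b > 0) return(params@Jcc)
        params@Jcm
    }
    H <- 0
    for (cc in seq_len(L)) for (r in seq_len(L)) {
        for (k in seq_len(nrow(offs))) {
            r2 <- r + offs[k, 1]; c2 <- cc + offs[k, 2]
            if (r2 >= 1 && r2 <= L && c2 >= 1 && c2 <= L) {
                if (c2 > cc || (c2 == cc && r2 > r))
                    H <- H + Jof(sig[r, cc], sig[r2, c2])
            } else {
                H <- H + Jof(sig[r, cc], 0L)
            }
        }
    }
    H + sum(params@lambdaArea * (state@cells$area - params@ATarget)^2)
}

# Disk rasterized independently of the fixtures module.
rasterDiskOracle <- function(side, radius) {
    ctr <- floor((side + 1) / 2)
    xs <- matrix(seq_len(side), side, side)
    ys <- t(xs)
    matrix(as.integer((xs - ctr)^2 + (ys - ctr)^2 <= radius^2), side)
}

# Small parameter set for fast unit tests.
tinyParams <- function(...) {
    referenceParams(latticeSide = 24L, ATarget = 9, pdeSubsteps = 64L, ...)
}

# A roughened multi-cell state plus smooth random fields, for
# property-style CPM tests.
roughState <- function(seed = 1, L = 24L, nCells = 4L, mcs = 5L, ...) {
    p <- referenceParams(latticeSide = L, ATarget = 9, seed = as.integer(seed),
                         ...)
    set.seed(p@seed)
    st <- initializeCells(nCells, "semi_random", p)
    f <- emptyFields(p)
    f@s <- matrix(runif(L * L), L)
    f@b <- matrix(runif(L * L), L)
    st <- monteCarloStep(st, f, p, mcs)
    list(state = st, fields = f, params = p)
}
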