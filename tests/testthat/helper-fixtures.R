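# Shared fixtures, built in code. The cache avoids re-simulating the same
# panel across test files within one run.
.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

tinyConfig <- function(...) {
  args <- list(seed = 101L, nL1Loci = 6L,
               hostCategories = c(mRNA = 8L, histone = 4L, MT = 2L,
                                  rRNA = 2L, lncRNA = 3L, circRNA_host = 2L),
               nReadsInput = 4000L, nReadsIP = 4000L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simConfig, args)
}

tinySim <- function() cached("tinySim", simulateGenome(tinyConfig()))
tinyReads <- function() cached("tinyReads", simulateReads(tinySim()))
tinyAln <- function() cached("tinyAln", emulateAlignment(tinyReads(), tinySim()))

# random small EM instance; every read keeps at least one positive weight
randomCompat <- function(K = sample(1:3, 1), n = sample(1:6, 1)) {
  W <- matrix(runif(n * K), n, K)
  mask <- matrix(runif(n * K) < 0.4, n, K)
  for (i in seq_len(n)) if (all(mask[i, ])) mask[i, sample(K, 1)] <- FALSE
  W[mask] <- 0
  W
}

# independent brute-force BH step-up (oracle; no p.adjust)
bruteForceBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# independent permutation generator (oracle; distinct from the package's)
permsOf <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], permsOf(v[-i])))
  out
}
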