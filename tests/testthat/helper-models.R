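# Small model builders and random instance generators used across tests.

# a model with every free distribution drawn from a flat Dirichlet
randomModel <- function(n, local = FALSE, seed = 1) {
  set.seed(seed)
  rdir <- function(k) { g <- rgamma(k, 1) + 1e-3; g / sum(g) }
  ME <- t(vapply(seq_len(n), function(i) rdir(4), numeric(4)))
  TR <- t(vapply(seq_len(n), function(i) {
    m <- if (local) rdir(4) else c(rdir(3), 0)
    c(m[1:3], if (local) m[4] else 0, rdir(2), rdir(2))
  }, numeric(8)))
  BG <- if (local) rdir(3) else c(rdir(2), 0)
  DIO <- if (local) c(rdir(2), rdir(2)) else numeric(4)
  newProfileHMM(ME, rdir(4), TR, BG, DIO, localMode = local)
}

randomDnaString <- function(K, seed = 1) {
  set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), K, replace = TRUE), collapse = "")
}

# a 1-position global model with deterministic transitions; emission on A
# with probability pA (remainder spread over C,G,T)
onePositionModel <- function(pA = 1) {
  ME <- matrix(c(pA, rep((1 - pA) / 3, 3)), 1, 4)
  TR <- matrix(c(.999999, .0000005, .0000005, 0, .5, .5, .5, .5), 1, 8)
  TR[1, 1:3] <- TR[1, 1:3] / sum(TR[1, 1:3])
  newProfileHMM(ME, rep(.25, 4), TR, c(1 - 1e-12, 1e-12, 0), numeric(4),
                localMode = FALSE, validate = FALSE)
}

# a near-deterministic global model that emits exactly `consensus`
railModel <- function(consensus, eps = 1e-9) {
  ch <- strsplit(consensus, "")[[1]]
  n <- length(ch)
  ME <- matrix(eps / 3, n, 4)
  ME[cbind(seq_len(n), match(ch, c("A", "C", "G", "T")))] <- 1 - eps
  TR <- matrix(c(1 - 2 * eps, eps, eps, 0, 1 - eps, eps, 1 - eps, eps),
               n, 8, byrow = TRUE)
  newProfileHMM(ME, rep(.25, 4), TR, c(1 - eps, eps, 0), numeric(4),
                localMode = FALSE)
}

# a local-mode model with trained-like transitions (a scanner's table, not
# the diffuse training start where Match mostly exits): used by hit tests
localScanModel <- function(ME, insert = rep(.25, 4)) {
  n <- nrow(ME)
  TR <- matrix(c(.93, .02, .02, .03, .5, .5, .5, .5), n, 8, byrow = TRUE)
  newProfileHMM(ME, insert, TR, c(.09, .01, .9),
                c(.9999, .0001, .9999, .0001), localMode = TRUE)
}

# thin bridges to package internals used by the trainer tests
cpp_loglik_for_tests <- function(model, seqs)
  plan7:::cpp_loglik(plan7:::.asCList(model), plan7:::.encodeSeqs(seqs))

.dirichletPenaltyTest <- function(model, priors)
  plan7:::.dirichletPenalty(model, priors)
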