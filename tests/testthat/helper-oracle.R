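# Independent brute-force oracle: enumerates every legal Plan 7 state path
# for a small model and sequence, accumulating the likelihood, per-(state,
# time) posteriors, and expected emission/transition usage.  Written
# directly from the path semantics (no dynamic programming), so it checks
# the DP engine without sharing code with it.

oracleEnumerate <- function(model, seq) {
  code <- plan7:::.encodeSeqs(seq)[[1]]
  K <- length(code)
  n <- modelLength(model)
  TR <- transitions(model)
  ME <- matchEmissions(model)
  IE <- insertEmissions(model)
  BG <- model@begin
  DIO <- model@deletionInOut
  local <- isLocal(model)
  eM <- function(p, d) if (d < 0) 1 else ME[p, d + 1]
  eI <- function(d) if (d < 0) 1 else IE[d + 1]
  entry <- function(p) {
    if (p == 1) return(BG[["BM"]])
    if (!local) return(0)
    BG[["BDI"]] * DIO[["dinContinue"]]^(p - 2) * DIO[["dinExit"]]
  }

  acc <- new.env()
  acc$L <- 0
  acc$postM <- matrix(0, K + 1, n); acc$postI <- matrix(0, K + 1, n)
  acc$postD <- matrix(0, K + 1, n)
  acc$ME <- matrix(0, n, 4); acc$IE <- numeric(4)
  acc$TR <- matrix(0, n, 8); acc$BG <- numeric(3); acc$DIO <- numeric(4)
  acc$ins <- numeric(n); acc$del <- numeric(n)

  # usage: list of records; each c(type, i, j, w) applied at path end
  finish <- function(prob, usage) {
    if (prob <= 0) return()
    acc$L <- acc$L + prob
    for (u in usage) {
      w <- prob * u$w
      switch(u$type,
             postM = { acc$postM[u$i, u$j] <- acc$postM[u$i, u$j] + w },
             postI = { acc$postI[u$i, u$j] <- acc$postI[u$i, u$j] + w },
             postD = { acc$postD[u$i, u$j] <- acc$postD[u$i, u$j] + w },
             ME = { acc$ME[u$i, u$j] <- acc$ME[u$i, u$j] + w },
             IE = { acc$IE[u$i] <- acc$IE[u$i] + w },
             TR = { acc$TR[u$i, u$j] <- acc$TR[u$i, u$j] + w },
             BG = { acc$BG[u$i] <- acc$BG[u$i] + w },
             DIO = { acc$DIO[u$i] <- acc$DIO[u$i] + w },
             ins = { acc$ins[u$i] <- acc$ins[u$i] + w },
             del = { acc$del[u$i] <- acc$del[u$i] + w })
    }
  }
  U <- function(type, i, j = 1, w = 1) list(type = type, i = i, j = j, w = w)
  emitU <- function(p, tau, d, atM) {
    us <- list()
    if (atM) {
      us <- c(us, list(U("postM", tau + 1, p)))
      if (d >= 0) us <- c(us, list(U("ME", p, d + 1)))
    } else {
      us <- c(us, list(U("postI", tau + 1, p), U("ins", p)))
      if (d >= 0) us <- c(us, list(U("IE", d + 1)))
    }
    us
  }

  # role: "M", "I" (just emitted at tau), or "D" (silent, at tau)
  walk <- function(role, p, tau, prob, usage) {
    if (role == "M") {
      if (tau == K) {
        if (p == n) {
          finish(prob * TR[n, "MM"], c(usage, list(U("TR", n, 1))))
          finish(prob * TR[n, "MD"], c(usage, list(U("TR", n, 3))))
          if (local)
            finish(prob * TR[n, "MDO"] * DIO[["doutExit"]],
                   c(usage, list(U("TR", n, 4), U("DIO", 4))))
        } else if (local) {
          finish(prob * TR[p, "MDO"] * DIO[["doutContinue"]]^(n - p) *
                   DIO[["doutExit"]],
                 c(usage, list(U("TR", p, 4), U("DIO", 3, w = n - p),
                               U("DIO", 4))))
        }
        # M -> I / M -> M need further emissions: dead ends at tau == K
        if (p < n)  # M -> D chain may still reach the end silently
          walk("D", p + 1, tau, prob * TR[p, "MD"],
               c(usage, list(U("TR", p, 3))))
        return()
      }
      d <- code[tau + 1]
      if (p < n)
        walk("M", p + 1, tau + 1,
             prob * TR[p, "MM"] * eM(p + 1, d),
             c(usage, list(U("TR", p, 1)), emitU(p + 1, tau + 1, d, TRUE)))
      walk("I", p, tau + 1, prob * TR[p, "MI"] * eI(d),
           c(usage, list(U("TR", p, 2)), emitU(p, tau + 1, d, FALSE)))
      if (p < n)
        walk("D", p + 1, tau, prob * TR[p, "MD"],
             c(usage, list(U("TR", p, 3))))
    } else if (role == "I") {
      if (tau == K) {
        if (p == n)
          finish(prob * TR[n, "IM"], c(usage, list(U("TR", n, 5))))
        return()
      }
      d <- code[tau + 1]
      if (p < n)
        walk("M", p + 1, tau + 1, prob * TR[p, "IM"] * eM(p + 1, d),
             c(usage, list(U("TR", p, 5)), emitU(p + 1, tau + 1, d, TRUE)))
      walk("I", p, tau + 1, prob * TR[p, "II"] * eI(d),
           c(usage, list(U("TR", p, 6)), emitU(p, tau + 1, d, FALSE)))
    } else {  # D, silent, currently at time tau
      usage <- c(usage, list(U("postD", tau + 1, p), U("del", p)))
      if (p == n) {
        if (tau == K)
          finish(prob * TR[n, "DM"], c(usage, list(U("TR", n, 7))))
        return()
      }
      if (tau < K) {
        d <- code[tau + 1]
        walk("M", p + 1, tau + 1, prob * TR[p, "DM"] * eM(p + 1, d),
             c(usage, list(U("TR", p, 7)), emitU(p + 1, tau + 1, d, TRUE)))
      }
      walk("D", p + 1, tau, prob * TR[p, "DD"],
           c(usage, list(U("TR", p, 8))))
    }
  }

  if (K >= 1) {
    d <- code[1]
    for (p in seq_len(n)) {
      en <- entry(p)
      if (en > 0) {
        us <- if (p == 1) list(U("BG", 1))
              else list(U("BG", 3), U("DIO", 1, w = p - 2), U("DIO", 2))
        walk("M", p, 1, en * eM(p, d), c(us, emitU(p, 1, d, TRUE)))
      }
    }
  }
  walk("D", 1, 0, BG[["BD"]], list(U("BG", 2)))

  list(L = as.numeric(acc$L), loglik = as.numeric(log(acc$L)),
       postM = acc$postM / acc$L, postI = acc$postI / acc$L,
       postD = acc$postD / acc$L,
       counts = list(ME = acc$ME / acc$L, IE = acc$IE / acc$L,
                     TR = acc$TR / acc$L, BG = acc$BG / acc$L,
                     DIO = acc$DIO / acc$L,
                     ins = acc$ins / acc$L, del = acc$del / acc$L))
}
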