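`%||%` <- function(a, b) if (is.null(a)) b else a

#  Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
#  state afterwards so library calls do not perturb user-level streams.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#  Sortable numeric key for chromosome labels: 1..22 numeric, then X, Y, MT,
#  then anything else in lexicographic order.
chrom_rank <- function(chr) {
  chr <- sub("^chr", "", as.character(chr))
  num <- suppressWarnings(as.numeric(chr))
  extra <- match(toupper(chr), c("X", "Y", "MT", "M"))
  out <- ifelse(!is.na(num), num, ifelse(!is.na(extra), 22 + extra, NA))
  if (anyNA(out)) {
    rest <- is.na(out)
    out[rest] <- 100 + xtfrm(chr[rest])
  }
  out
}

#  Derive a per-task 32-bit seed from a base seed and an index.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(i)) %% 2147483647)
}
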