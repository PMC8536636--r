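## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

warn2 <- function(...) warning(..., call. = FALSE)

## sample SD (n-1), the convention used for every stored normalization
## constant (ref_gene_sd, ref_rawscore_sd, ref_sumz_sd)
sample_sd <- function(x) stats::sd(x)

## column-wise sample SDs without building a data.frame
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop2("need >= 2 rows to compute a sample SD")
  mu <- colMeans(m)
  sqrt((colSums(m^2) - n * mu^2) / (n - 1))
}

## adjusted Rand index between two label vectors (gray/0 labels should be
## removed by the caller when they are not part of the comparison)
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop2("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## deterministic child RNG seed derived from a user seed and a stream id,
## kept below 2^31
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483647L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
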