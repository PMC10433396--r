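# deterministic fixture: two guilds of positively co-varying taxa driven by
# sample-level latent factors, plus independent background noise taxa
guild_counts <- function(n_samples = 20, guild_size = 10, n_background = 5,
                         seed = 99) {
  set.seed(seed)
  f1 <- exp(rnorm(n_samples, 0, 1))
  f2 <- exp(rnorm(n_samples, 0, 1))
  mk_taxon <- function(f) rpois(n_samples, 40 * f * exp(rnorm(1, 0, 0.1)))
  g1 <- vapply(seq_len(guild_size), function(i) mk_taxon(f1),
               numeric(n_samples))
  g2 <- vapply(seq_len(guild_size), function(i) mk_taxon(f2),
               numeric(n_samples))
  bg <- vapply(seq_len(n_background),
               function(i) rpois(n_samples, 30), numeric(n_samples))
  m <- cbind(g1, g2, bg) + 1L
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      c(paste0("g1_", seq_len(guild_size)),
                        paste0("g2_", seq_len(guild_size)),
                        paste0("bg_", seq_len(n_background))))
  storage.mode(m) <- "integer"
  m
}
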