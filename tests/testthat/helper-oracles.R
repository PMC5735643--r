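# Brute-force oracles, written as direct transliterations of the defining
# formulas (explicit loops, no shared code with the implementation), plus a
# tiny hand-built survey fixture.

oracle_levins <- function(p, n_states) {
  p <- p / sum(p)
  ssq <- 0
  for (v in p) ssq <- ssq + v * v
  B <- 1 / ssq
  (B - 1) / (n_states - 1)
}

oracle_pianka <- function(p, q) {
  p <- p / sum(p)
  q <- q / sum(q)
  num <- 0; sp <- 0; sq <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * q[i]
    sp <- sp + p[i]^2
    sq <- sq + q[i]^2
  }
  num / sqrt(sp * sq)
}

oracle_chisq <- function(counts, prob = rep(1 / length(counts), length(counts))) {
  E <- sum(counts) * prob
  s <- 0
  for (i in seq_along(counts)) s <- s + (counts[i] - E[i])^2 / E[i]
  s
}

oracle_g <- function(tab) {
  n <- sum(tab)
  g <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    if (tab[i, j] > 0) g <- g + tab[i, j] * log(tab[i, j] / e)
  }
  2 * g
}

# exact mean overlap over all joint permutations of two rows
oracle_perm_mean_overlap <- function(a, b) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  pa <- perms(a); pb <- perms(b)
  vals <- c()
  for (x in pa) for (y in pb) vals <- c(vals, oracle_pianka(x, y))
  mean(vals)
}

# Five specimens (one void), hand-countable items
tiny_specimens <- function() {
  validate_specimens(data.frame(
    specimen_id = c("a1", "a2", "a3", "b1", "b2"),
    species = c("S. gibbus", "S. gibbus", "S. gibbus",
                "S. rhombeus", "S. rhombeus"),
    sex = c("male", "female", "female", "female", "undetermined"),
    total_length_mm = c(110, 120, 130, 300, 310),
    total_weight_g = c(90, 100, 120, 700, 720),
    gutted_weight_g = c(80, 88, 105, 640, 650),
    stomach_weight_g = c(3, 4, 5, 20, 2),
    capture_date = c("2012-03-01", "2012-03-02", "2011-09-10",
                     "2012-04-05", "2011-08-01"),
    interval = c("18:00", "21:00", "12:00", "03:00", "09:00"),
    repletion = c("full", "partly_full", "full", "full", "void"),
    stringsAsFactors = FALSE))
}

tiny_items <- function(specimens = tiny_specimens()) {
  validate_stomach_items(data.frame(
    specimen_id = c("a1", "a1", "a2", "a3", "b1", "b1"),
    category = c("fish", "insect", "fish", "plant", "fish", "crustacean"),
    volume = c(3, 1, 2, 0.5, 10, 0.4),
    stringsAsFactors = FALSE), specimens)
}
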