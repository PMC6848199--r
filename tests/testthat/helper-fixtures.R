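# Shared fixtures: tiny timelines and random-profile generators.

tl3 <- function() timeline(c("A", "B", "C"), c(100, 50, 10), root_age = 150)

tl4 <- function() timeline(c("A", "B", "C", "D"), c(400, 300, 200, 100),
                           root_age = 500)

tl16 <- function() default_timeline()

# Random origination profile over k taxa with all entries positive.
random_profile <- function(k) {
  p <- stats::rgamma(k, shape = 1) + 0.05
  p / sum(p)
}

# Random cumulative curve (counts of n genes over k taxa).
random_cum <- function(k, n = 200) {
  counts <- as.vector(stats::rmultinom(1, n, random_profile(k)))
  cumsum(counts) / n
}

# Shift an origination profile `shift` taxa toward the root (older).
shift_rootward <- function(pi, shift) {
  k <- length(pi)
  out <- numeric(k)
  for (i in seq_len(k)) {
    j <- max(i - shift, 1)
    out[j] <- out[j] + pi[i]
  }
  out
}

# class_ages-like tibble from named age-vector list (no coverage attr).
as_class_ages <- function(age_list) {
  purrr::imap_dfr(age_list, function(v, nm) {
    tibble::tibble(class = nm, gene_id = paste0(nm, "_", seq_along(v)),
                   taxon_index = as.integer(v))
  })
}

# Three well-separated profile families on 16 taxa for planted-structure
# simulations: early-, mid- and late-weighted origination.
planted_profiles <- function() {
  old <- c(24, 14, 10, 12, 4, 12, 8, 5, 3, 3, 1, 1, 1, 1, 0.5, 0.5)
  mid <- c(2, 2, 3, 5, 3, 10, 16, 16, 12, 12, 6, 5, 4, 2, 1, 1)
  young <- c(1, 1, 1, 1, 1, 2, 3, 4, 5, 8, 8, 12, 18, 18, 9, 8)
  list(old = old / sum(old), mid = mid / sum(mid), young = young / sum(young))
}
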