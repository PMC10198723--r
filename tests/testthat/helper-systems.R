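# reference game used throughout: N = 6, M = 3, b = 1, c = 0.1
ref_game <- function() crsd_game(N = 6, M = 3, b = 1, c = 0.1)

linear_system <- function(u, eps = 0.1, game = ref_game())
  crsd_system(game, linear_feedback(u), eps)

sigmoid_system <- function(T, beta = 10, eps = 0.1, game = ref_game())
  crsd_system(game, exponential_feedback(T, beta), eps)

# random valid game draw (integer N in [3, nmax], 1 < M < N, 0 < c < b)
random_game <- function(nmax = 20) {
  N <- sample(3:nmax, 1)
  M <- if (N == 3) 2L else sample(2:(N - 1), 1)
  b <- stats::runif(1, 0.5, 2)
  crsd_game(N, M, b, c = stats::runif(1, 0.05, 0.95) * b)
}

stable_set_of <- function(system) {
  fp <- enumerate_fixed_points(system)
  fp[fp$stability == "stable", c("x", "r")]
}
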