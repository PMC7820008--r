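# programmatic fixtures shared across the test files

# one-channel spectra tibble evaluated exactly on the model curve
model_spectrum <- function(lnC = 5, alpha = -2.5, bumps = NULL,
                           channel = "C3", fmax = 62.5) {
  synth_spectrum(lnC = lnC, alpha = alpha, bumps = bumps, noise_sd = 0,
                 fmin = 0.25, fmax = fmax, channel = channel)
}

bump <- function(center, height, width) {
  data.frame(center = center, height = height, width = width)
}

# small all-N2 recording with white Gaussian noise
noise_recording <- function(duration_s = 100, sfreq = 100, sd = 1,
                            seed = 42, channels = "C3") {
  set.seed(seed)
  sig <- lapply(stats::setNames(channels, channels),
                function(ch) rnorm(duration_s * sfreq, 0, sd))
  nremspec:::new_recording(
    sig, sfreq,
    epoch_stages = rep("N2", ceiling(duration_s / 20)),
    artifact_mask = rep(FALSE, ceiling(duration_s / 4))
  )
}

# independent flood-fill connected components (oracle for rueger_test)
components_bruteforce <- function(nodes, edges) {
  nbr <- stats::setNames(lapply(nodes, function(n) {
    unique(c(edges$to[edges$from == n], edges$from[edges$to == n]))
  }), nodes)
  seen <- character(0)
  comps <- list()
  for (n in nodes) {
    if (n %in% seen) next
    queue <- n
    comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, intersect(nbr[[v]], nodes))
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- comp
  }
  comps
}
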