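# Shared fixtures: seeded images and small networks, built in code.

test_image <- function(h = 16, w = 16, seed = 42, channels = 3) {
  set.seed(seed)
  array(runif(h * w * channels) * 255, dim = c(h, w, channels))
}

test_net <- function(seed = 1, padding = "circular") {
  build_toy_net(toy_net_spec(seed = seed, padding = padding))
}

# Fast dream settings for unit tests (acceptance uses the full defaults).
fast_config <- function(layer_id = "relu3", ...) {
  dream_config(layer_id, octaves = 2L, octave_scale = 2, iterations = 4L,
               jitter = 4L, seed = 11L, ...)
}

# Direct nested-loop convolution, independent of the C++ path.
conv_oracle <- function(input, w, bias, padding = "circular") {
  H <- dim(input)[1]; W <- dim(input)[2]; Cin <- dim(input)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  ph <- kh %/% 2; pw <- kw %/% 2
  out <- array(0, dim = c(H, W, Cout))
  for (oc in seq_len(Cout)) for (x in seq_len(W)) for (y in seq_len(H)) {
    acc <- bias[oc]
    for (ic in seq_len(Cin)) for (kx in seq_len(kw)) for (ky in seq_len(kh)) {
      yy <- y + ky - 1 - ph; xx <- x + kx - 1 - pw
      if (padding == "circular") {
        yy <- ((yy - 1) %% H) + 1; xx <- ((xx - 1) %% W) + 1
      } else if (yy < 1 || yy > H || xx < 1 || xx > W) next
      acc <- acc + input[yy, xx, ic] * w[ky, kx, ic, oc]
    }
    out[y, x, oc] <- acc
  }
  out
}

# Brute-force within-subject sums of squares from explicit mean
# decomposition; independent of rm_anova_2way.
ss_oracle <- function(cells) {
  # cells: data.frame(s, a, b, y), complete and balanced
  g <- mean(cells$y)
  dev <- function(f) tapply(cells$y, cells[[f]], mean) - g
  n <- nlevels(cells$s); na <- nlevels(cells$a); nb <- nlevels(cells$b)
  ss <- c(
    subjects = na * nb * sum(dev("s")^2),
    A = n * nb * sum(dev("a")^2),
    B = n * na * sum(dev("b")^2)
  )
  resid2 <- function(ft) {
    m <- tapply(cells$y, cells[ft], mean)
    e1 <- dev(ft[1]); e2 <- dev(ft[2])
    sum((m - outer(e1, rep(0, length(e2)), "+") -
           outer(rep(0, length(e1)), e2, "+") - g)^2)
  }
  ss["A:B"] <- n * resid2(c("a", "b"))
  ss["A:subjects"] <- nb * resid2(c("a", "s"))
  ss["B:subjects"] <- na * resid2(c("b", "s"))
  ss["total"] <- sum((cells$y - g)^2)
  ss["A:B:subjects"] <- ss["total"] - sum(ss[c("subjects", "A", "B", "A:B",
                                               "A:subjects", "B:subjects")])
  ss
}
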