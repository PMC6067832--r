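# Small-geometry configurations and shared fixtures for fast unit tests.
# Fixtures are memoized per test session in `.fixtures`.

.fixtures <- new.env(parent = emptyenv())

# compact model: coarse sheets, same architecture
smallConfig <- function(...) {
  cfg <- gcalConfig(...)
  cfg$sheets$retina_density <- 10
  cfg$sheets$lgn_density <- 10
  cfg$sheets$v1_density <- 16
  cfg
}

smallModel <- function(seed = 1L, ...) buildModel(smallConfig(...), seed)

# tiny model for brute-force oracles (5x5 LGN-scale sheets)
tinyConfig <- function() {
  cfg <- gcalConfig()
  cfg$sheets$retina_density <- 5
  cfg$sheets$lgn_density <- 5
  cfg$sheets$v1_density <- 5
  cfg
}

# memoize an expensive fixture across test files
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# brute-force reference for one full presentation (no learning), computed
# entirely in R from the engine's exported structure; row-major like the
# engine (flat index k = r * n + c)
referencePresent <- function(model, image) {
  st <- gcalsim:::net_struct(model@ptr)
  n_ret <- st$n_ret; n_lgn <- st$n_lgn; n_v1 <- st$n_v1
  img <- as.numeric(t(image))           # row-major
  hw <- st$dog_hw; kw <- 2 * hw + 1; o <- st$ret_lgn_off
  drive <- numeric(n_lgn^2)
  for (r in 0:(n_lgn - 1)) for (c in 0:(n_lgn - 1)) {
    s <- 0
    for (dr in -hw:hw) for (dc in -hw:hw) {
      k <- st$dog_k[(dr + hw) * kw + (dc + hw) + 1]
      if (k != 0)
        s <- s + k * img[(r + o + dr) * n_ret + (c + o + dc) + 1]
    }
    drive[r * n_lgn + c + 1] <- s
  }
  channel <- function(sign) {
    raw <- pmax(sign * st$gamma_L * drive, 0)
    if (st$gamma_S > 0) {
      ghw <- st$gc_hw; gkw <- 2 * ghw + 1
      pool <- numeric(n_lgn^2)
      for (r in 0:(n_lgn - 1)) for (c in 0:(n_lgn - 1)) {
        s <- 0; ks <- 0
        for (dr in -ghw:ghw) for (dc in -ghw:ghw) {
          rr <- r + dr; cc <- c + dc
          if (rr < 0 || rr >= n_lgn || cc < 0 || cc >= n_lgn) next
          k <- st$gc_k[(dr + ghw) * gkw + (dc + ghw) + 1]
          if (k != 0) { s <- s + k * raw[rr * n_lgn + cc + 1]; ks <- ks + k }
        }
        pool[r * n_lgn + c + 1] <- if (ks > 0) s / ks else 0
      }
      pmin(pmax(st$lgn_scale * raw / (st$gc_k0 + st$gamma_S * pool), 0), 1)
    } else {
      pmin(pmax(st$lgn_scale * raw / st$gc_k0, 0), 1)
    }
  }
  on <- channel(+1); off <- channel(-1)
  lgn_joint <- c(on, off)
  projSum <- function(p, src) {
    out <- numeric(length(p$off) - 1)
    for (i in seq_along(out)) {
      a <- p$off[i] + 1; b <- p$off[i + 1]
      if (b >= a) {
        kk <- a:b
        out[i] <- sum(p$w[kk] * src[p$idx[kk] + 1])
      }
    }
    out
  }
  affd <- projSum(st$aff, lgn_joint)
  slope <- st$slope
  f <- function(x) pmin(pmax(slope * x, 0), 1)
  v1 <- f(st$aff$strength * affd - st$theta)
  for (step in seq_len(st$settle_steps)) {
    e <- projSum(st$exc, v1)
    i <- projSum(st$inh, v1)
    v1 <- f(st$aff$strength * affd + st$exc$strength * e -
              st$inh$strength * i - st$theta)
  }
  list(lgn_on = on, lgn_off = off, v1 = v1, affdrive = affd)
}
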