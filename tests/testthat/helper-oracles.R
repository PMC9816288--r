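# shared fixtures and independent oracles for the test suite

# canonical population input-function parameter set (normalized-curve scale)
pop_params <- function() {
  feng_params(tau = 0.72, A1 = 15.9, A2 = 0.02, A3 = 0.02,
              lam1 = 17.8, lam2 = 0.18, lam3 = 0.01)
}

# noiseless Feng curve sampled at frame mid-times of a schedule
curve_on_schedule <- function(params, schedule = default_schedule(),
                              label = "IDIF") {
  mids <- schedule_mid_times_min(schedule)
  sampled_curve(schedule$start / 60, (schedule$start + schedule$duration) / 60,
                feng_eval(params, mids), label = label)
}

# plain trapezoid on an (x, y) grid — quadrature oracle
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# fixed-step RK4 integration of the irreversible 2TCM ODE system
#   dC1/dt = K1 Cp - (k2 + k3) C1,  dC2/dt = k3 C1,  Ct = C1 + C2
# independent of the closed-form convolution it serves as oracle for
rk4_2tcm <- function(aif_params, kp, t_end, dt = 0.002) {
  half <- seq(0, t_end, by = dt / 2)
  cp <- feng_eval(aif_params, half)
  n <- (length(half) - 1) %/% 2
  beta <- kp$k2 + kp$k3
  c1 <- numeric(n + 1); c2 <- numeric(n + 1)
  for (i in seq_len(n)) {
    cp0 <- cp[2 * i - 1]; cph <- cp[2 * i]; cp1 <- cp[2 * i + 1]
    y1 <- c1[i]
    k1a <- kp$K1 * cp0 - beta * y1
    k2a <- kp$K1 * cph - beta * (y1 + dt / 2 * k1a)
    k3a <- kp$K1 * cph - beta * (y1 + dt / 2 * k2a)
    k4a <- kp$K1 * cp1 - beta * (y1 + dt * k3a)
    c1[i + 1] <- y1 + dt / 6 * (k1a + 2 * k2a + 2 * k3a + k4a)
    # c2 integrates k3 * c1 (RK4 on a known integrand = Simpson)
    m1 <- kp$k3 * y1
    mh <- kp$k3 * (y1 + dt / 2 * k1a)   # midpoint state estimate
    m4 <- kp$k3 * c1[i + 1]
    c2[i + 1] <- c2[i] + dt / 6 * (m1 + 4 * mh + m4)
  }
  t <- seq(0, t_end, by = dt)
  list(t = t, ct = c1 + c2, c1 = c1, c2 = c2,
       cp = cp[seq(1, length(half), by = 2)])
}

# cached expensive fixtures, shared across test files
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

noiseless_config <- function() population_config(noise_level = 0)

small_population <- function() fixture("small_population", function()
  generate_population(4, noiseless_config(), seed = 42))

small_pbif <- function() fixture("small_pbif", function()
  build_pbif(lapply(small_population(), `[[`, "idif"), seed = 7))
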