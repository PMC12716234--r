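# shared fixtures: setups and small hand-made contours
ref <- reference_setup()
dopc_setup <- channel_setup(20, 0.04, viscosity_mpa_s = 6.3)

square_contour <- function(side = 1) {
  rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
}

triangle_contour <- rbind(c(0, 0), c(4, 0), c(1, 3))

# 4-pointed star: polygon area 4, convex hull (the diamond) area 8
star_contour <- rbind(c(2, 0), c(0.5, 0.5), c(0, 2), c(-0.5, 0.5),
                      c(-2, 0), c(-0.5, -0.5), c(0, -2), c(0.5, -0.5))

# star-shaped random simple polygon (radius perturbed smoothly in angle)
random_blob <- function(n = 80, wobble = 0.25) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 10 * (1 + wobble * (sin(3 * th + runif(1, 0, 2 * pi)) * runif(1) +
                             cos(5 * th) * runif(1, 0, 0.5)))
  cbind(r * cos(th), r * sin(th))
}
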