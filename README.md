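# carpofem

A desk-scale finite-element pipeline for a question in hominoid
locomotor evolution: **does a fused scaphoid-centrale withstand
knuckle-walking loads better than an unfused one?** African apes and
humans share the bony fusion of the os centrale to the scaphoid — one of
the few clear skeletal synapomorphies of that clade — and the leading
functional explanation is that the fusion stiffens the load path from
the metacarpals through the carpus into the radius during
knuckle-walking. `carpofem` is for biomechanists and biological
anthropologists who want a fully scripted, seeded version of that
experiment: synthetic scaphoid / os centrale / capitate geometries in
fused and unfused variants, linear-elastic multi-body models with
non-separation sliding contact, ligament and foundation springs, and a
statistical comparison of mesh-weighted stress between variants.

## The model in brief

Each bone is a cancellous tetrahedral core (E = 0.5 GPa, ν = 0.30)
wrapped in cortical (E = 10 GPa, ν = 0.22) and cartilage (E = 7 MPa,
ν = 0.30, t = 0.55 mm) membrane layers. Articular contacts are
non-separating and frictionless: for each coincident node pair
(u_A − u_B)·n = 0 along the contact normal, tangential sliding free.
The scapho(centrale)capitate ligament is a 40 N/mm set of parallel
spring strands — routed serially through the centrale in unfused
models. Lateral support from lunate, hamate and trapezoid is an elastic
foundation of 20.5 N/mm per patch; distal facets are fixed. Each
species is loaded with F = 0.2·m·g (20% of body weight, one forelimb's
share in quadrupedalism) along the proximodistal axis, with a 5° tilt
as a sensitivity case.

Per bone, the pipeline reports element-size-weighted von Mises
statistics — the mesh-weighted arithmetic mean MWAM = Σvᵢwᵢ/Σwᵢ and the
mesh-weighted median MWM (cumulative-weight rule) — and compares fused
against unfused MWAM across species with Welch's two-sample *t*-test
(Welch–Satterthwaite df) after a pooled Shapiro-Wilk normality check.

## Worked example

```r
library(carpofem)

compute_total_load(170.4)   # G. gorilla: 20% body weight, standard gravity
#> [1] 334.21

cfg <- study_config(seed = 1)
res <- solve_carpal_model(cfg, mass = 59.7, variant = "unfused",
                          angle = 0, seed = 42)
res$mesh
#> carpal_mesh (unfused): 3 bodies, 3975 nodes, 18144 tetrahedra, 3448 boundary triangles
#> bodies: scaphoid, centrale, capitate

res$summary[, c("body_name", "mwam", "mwm", "q25", "q75", "max")]
#>  body_name   mwam    mwm    q25    q75     max
#>   scaphoid 0.8776 0.6145 0.4521 1.1012  7.4483
#>   centrale 1.3467 0.6406 0.2983 1.7766 11.5180
#>   capitate 0.4444 0.2629 0.1856 0.5362  5.9813
```

All values are MPa. The centrale — the small bone relaying part of the
scaphoid's load into the capitate across two sliding joints — carries
the highest mesh-weighted stress and the large capitate the lowest. The
full experiment (5 species × fused/unfused × 0°/5°) runs with
`run_study()`:

```r
report <- run_study(study_config(angles = c(0, 5), seed = 1))
report
#> study_report: 5 species x 2 variants x 2 angles
#> fused vs unfused (Welch):
#>      bone angle mean_fused mean_unfused          t       df       p_t
#>  scaphoid     0  0.8763776    0.8999283 -0.1364513 7.993117 0.8948387
#>  capitate     0  0.4394860    0.4541435 -0.1684322 7.991317 0.8704282
#>  scaphoid     5  0.9169989    0.9687835 -0.2824617 7.972652 0.7847838
#>  capitate     5  0.4490822    0.4669718 -0.2005406 7.987726 0.8460697
```

Negative *t* means fused models carry less stress; in the default
synthetic study the fused scaphoid-centrale is below its unfused
counterpart for **every** species at both load angles (the
between-species size spread keeps the pooled *t* modest). A
command-line interface wraps the same functions:

```sh
exec/carpofem run --config study.yaml --outdir out/   # VTU + CSV outputs
exec/carpofem verify                                  # analytic fixtures
exec/carpofem report --outdir out/                    # re-derive statistics
```

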