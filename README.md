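# vitreokin

Compartmental pharmacokinetic modelling of drug delivery to the vitreous
humor from a sustained-release hydrogel depot.

Treating posterior-segment eye disease (endophthalmitis prophylaxis,
macular edema, AMD) requires therapeutic drug levels in the vitreous, but
every administration route — topical drops, subconjunctival injection,
intravitreal injection, subretinal injection — trades invasiveness
against bioavailability. `vitreokin` is for ocular drug-delivery
researchers who want to compare these routes *in silico* for a
sustained-release depot: a thermo-responsive PNIPAAm-PEG-DA hydrogel
loaded with vancomycin, whose in vitro release is well described by a
logarithmic decay of the gel's drug concentration.

## The model

The depot input function is the drug concentration remaining in the
hydrogel,

```
C_H(t) = clamp( a ln t + b , 0, b ),    a = −4.709 mg/mL per log-hour,
                                        b =  34.822 mg/mL,
```

held at `b` below 1 h and clamped at zero beyond
`t_zero = exp(−b/a) ≈ 1628 h` (complete release). Each route is a linear
compartmental system of well-mixed tissue pools (all first-order rates in
hr⁻¹, backflow set to zero, unit surface areas so amounts and
concentrations coincide):

```
dC_i/dt = Σ_j k_{j→i} C_j − ( Σ_j k_{i→j} + k_elim,i ) C_i + [i = entry] · k_in · C_H(t)
```

with transfer constants taken from an ocular pharmacokinetics literature
set (sclera 0.05472, choroid/retina 1.782, vitreous 0.0234,
RPE 0.000936, cornea 0.0216, conjunctiva 0.0018, aqueous chamber 0.0189,
iris/ciliary outflow 3.6; vitreous elimination 0.008208; systemic
absorption 0.0329 hr⁻¹). The depot coupling rate `k_in` has no
literature value; it is calibrated once so that the intravitreal model's
peak vitreous concentration equals 0.34 mg/mL, and the same `k_in` is
then shared by all four routes, making their predictions genuine rather
than fitted. Simulation uses a stiff-capable adaptive solver (lsoda) from
zero initial concentrations; the quantities of interest are the peak
vitreous concentration, its timing, and the first crossing of the
therapeutic thresholds 0.007 and 0.024 mg/mL.

## Worked example

```r
library(vitreokin)

p   <- default_parameters()
kin <- calibrate_kin(p, target_peak = 0.34)   # one-step, by linearity
run_report(params = set_kin(p, kin))
```

```
calibrated kin: 0.00140334 hr^-1
            route peak_vitreous_mg_ml t_peak_h time_to_0.007_h time_to_0.024_h
1         topical               0.693      321            28.9            42.9
2 subconjunctival               1.063      249            11.1            17.5
3    intravitreal               0.340       27             0.1             0.5
4      subretinal               1.703      236             4.2             7.7
```

Reading the table: the intravitreal depot reaches the therapeutic level
(0.007 mg/mL) within six minutes and peaks at the calibration target;
the subconjunctival route needs ~11 h and the topical route ~29 h to
become therapeutic, and the topical route is the slowest to peak
(~320 h) because drug trickles through both the corneal and
conjunctival–scleral pathways. All four routes achieve therapeutic
vitreous levels. The high late peaks of the indirect routes reflect the
slow vitreous elimination constant (0.008208 hr⁻¹): once drug has
percolated through the outer tissues the vitreous acts almost as an
integrator. Individual pieces are available separately —
`build_model()`, `simulate_system()`, `find_threshold_crossing()`,
`find_peak()` — and `fit_log_release()` /
`generate_release_profile()` fit and synthesise release profiles
(e.g. recovering the 84% cumulative release at 504 h and an
encapsulation efficiency of 57% from 34 of 60 mg retained).

A thin command-line wrapper ships in `inst/cli/vitreokin`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","vitreokin",package="vitreokin"))')" \
    simulate --route all --horizon 1500 --out out/
```

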