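# Default channel gating kinetics for the CA3 pyramidal neuron models.
#
# These parameterizations are the package's own defaults, written in the
# standard CA3/CA1 Hodgkin-Huxley style (Boltzmann steady states, bell-shaped
# voltage-dependent time constants) and tuned so that the base model
# reproduces the signature somatodendritic electrophysiology of CA3b
# pyramidal cells. Kinetics are data: supply an alternative file to
# load_kinetics() to change any of them.
#
# Gate kinds:
#   v   : inf = 1/(1+exp((vhalf - v)/k)); tau(v) = base + amp /
#         (exp((v - vhalf)/ka) + exp(-(v - vhalf)/kb))   [ms]
#   ca  : inf = 1/(1+(kd/ca)^nhill); constant tau        [SK]
#   vca : inf = 1/(1+exp(-(v - vh)/k)), vh = vh0 - sh*log10(ca/caref);
#         constant tau                                   [BK]
#
# Current laws: ohmic (erev mV) or ghk (calcium; p_factor converts the
# density parameter in mS/cm^2 into a GHK permeability in cm/s).
celsius: 34
channels:
  NaF:
    law: ohmic
    erev: 50
    gates:
      - {name: m, exponent: 3, kind: v,
         inf: {vhalf: -36.5, k: 6.5},
         tau: {base: 0.05, amp: 0.2, vhalf: -36.5, ka: 10.0, kb: 10.0}}
      - {name: h, exponent: 1, kind: v,
         inf: {vhalf: -50.0, k: -3.5},
         tau: {base: 0.5, amp: 30.0, vhalf: -55.0, ka: 9.0, kb: 9.0}}
  KDR:
    law: ohmic
    erev: -91
    gates:
      - {name: n, exponent: 2, kind: v,
         inf: {vhalf: -20.0, k: 9.0},
         tau: {base: 1.0, amp: 3.0, vhalf: -25.0, ka: 15.0, kb: 15.0}}
  KA_prox:
    law: ohmic
    erev: -91
    gates:
      - {name: a, exponent: 1, kind: v,
         inf: {vhalf: -15.0, k: 12.0},
         tau: {base: 0.2, amp: 1.0, vhalf: -30.0, ka: 15.0, kb: 15.0}}
      - {name: b, exponent: 1, kind: v,
         inf: {vhalf: -56.0, k: -6.0},
         tau: {base: 2.0, amp: 20.0, vhalf: -60.0, ka: 12.0, kb: 12.0}}
  KA_dist:
    law: ohmic
    erev: -91
    gates:
      - {name: a, exponent: 1, kind: v,
         inf: {vhalf: -42.0, k: 5.0},
         tau: {base: 0.1, amp: 0.2, vhalf: -40.0, ka: 15.0, kb: 15.0}}
      - {name: b, exponent: 1, kind: v,
         inf: {vhalf: -60.0, k: -6.0},
         tau: {base: 5.0, amp: 20.0, vhalf: -60.0, ka: 12.0, kb: 12.0}}
  KM:
    law: ohmic
    erev: -91
    gates:
      - {name: m, exponent: 1, kind: v,
         inf: {vhalf: -35.0, k: 6.0},
         tau: {base: 20.0, amp: 120.0, vhalf: -35.0, ka: 15.0, kb: 15.0}}
  HCN:
    law: ohmic
    erev: -30
    gates:
      - {name: h, exponent: 1, kind: v,
         inf: {vhalf: -82.0, k: -8.0},
         tau: {form: sigmoid, base: 120.0, amp: 2500.0, vhalf: -80.0,
               k: 4.0}}
  CaL:
    law: ghk
    p_factor: 1.0e-4
    gates:
      - {name: m, exponent: 2, kind: v,
         inf: {vhalf: -12.0, k: 7.0},
         tau: {base: 0.5, amp: 2.0, vhalf: -15.0, ka: 12.0, kb: 12.0}}
  CaT:
    law: ghk
    p_factor: 2.5e-4
    gates:
      - {name: m, exponent: 2, kind: v,
         inf: {vhalf: -37.0, k: 5.5},
         tau: {base: 2.0, amp: 15.0, vhalf: -55.0, ka: 14.0, kb: 14.0}}
      - {name: h, exponent: 1, kind: v,
         inf: {vhalf: -75.0, k: -5.0},
         tau: {base: 10.0, amp: 80.0, vhalf: -72.0, ka: 12.0, kb: 12.0}}
  CaN:
    law: ghk
    p_factor: 1.0e-4
    gates:
      - {name: m, exponent: 2, kind: v,
         inf: {vhalf: -18.0, k: 7.0},
         tau: {base: 1.0, amp: 4.0, vhalf: -25.0, ka: 14.0, kb: 14.0}}
      - {name: h, exponent: 1, kind: v,
         inf: {vhalf: -40.0, k: -12.0},
         tau: {base: 70.0, amp: 0.0, vhalf: -40.0, ka: 12.0, kb: 12.0}}
  SK:
    law: ohmic
    erev: -91
    gates:
      - {name: z, exponent: 1, kind: ca,
         kd: 5.0e-4, nhill: 4.0, tau: 10.0}
  BK:
    law: ohmic
    erev: -91
    gates:
      - {name: z, exponent: 1, kind: vca,
         vh0: -28.0, sh: 40.0, caref: 1.0e-2, k: 7.0, tau: 0.6}
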