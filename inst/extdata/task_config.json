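{
  "defaults": {
    "intertrial_interval": 10.0,
    "blackout_delay": 2.0,
    "duration_multiplier": 25.0,
    "min_duration": 25.0
  },
  "subjects": [
    {"subject_id": 1, "f_lead": 217.4, "P_lead": 1.0, "f_trail": 10.0, "P_trail": 1.0,
     "f_u_beta": 20.0, "f_l_alpha": 125.9, "P_l_ab": 0.4, "P_u_ab": 3.9,
     "f_l_lambda": 31.6, "f_u_lambda": 79.4, "P_l_lambda": 8.1},
    {"subject_id": 2, "f_lead": 196.1, "P_lead": 1.0, "f_trail": 10.0, "P_trail": 1.0,
     "f_u_beta": 35.5, "f_l_alpha": 100.0, "P_l_ab": 0.4, "P_u_ab": 3.9,
     "f_l_lambda": 63.1, "f_u_lambda": 125.9, "P_l_lambda": 4.1},
    {"subject_id": 3, "f_lead": 250.0, "P_lead": 1.0, "f_trail": 10.0, "P_trail": 1.0,
     "f_u_beta": 44.7, "f_l_alpha": 158.5, "P_l_ab": 0.4, "P_u_ab": 3.9,
     "f_l_lambda": 79.4, "f_u_lambda": 158.5, "P_l_lambda": 4.1},
    {"subject_id": 4, "f_lead": 200.0, "P_lead": 1.0, "f_trail": 10.0, "P_trail": 1.0,
     "f_u_beta": 31.6, "f_l_alpha": 100.0, "P_l_ab": 0.4, "P_u_ab": 3.9,
     "f_l_lambda": 50.1, "f_u_lambda": 79.4, "P_l_lambda": 4.1},
    {"subject_id": 5, "f_lead": 250.0, "P_lead": 1.0, "f_trail": 10.0, "P_trail": 1.0,
     "f_u_beta": 28.2, "f_l_alpha": 125.9, "P_l_ab": 0.4, "P_u_ab": 3.9,
     "f_l_lambda": 39.8, "f_u_lambda": 100.0, "P_l_lambda": 4.1},
    {"subject_id": 6, "f_lead": 163.9, "P_lead": 1.0, "f_trail": 10.0, "P_trail": 1.0,
     "f_u_beta": 25.1, "f_l_alpha": 79.4, "P_l_ab": 0.4, "P_u_ab": 3.9,
     "f_l_lambda": 39.8, "f_u_lambda": 100.0, "P_l_lambda": 4.1}
  ]
}
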