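method,quantity,angle_deg,value
Method 1,von_mises,0,7.447
Method 1,von_mises,45,6.356
Method 1,von_mises,90,5.67
Method 1,von_mises,135,6.371
Method 2,von_mises,0,8.06
Method 2,von_mises,45,6.694
Method 2,von_mises,90,5.858
Method 2,von_mises,135,6.082
Method 3,von_mises,0,7.520
Method 3,von_mises,45,6.460
Method 3,von_mises,90,5.335
Method 3,von_mises,135,5.444
Method 4,von_mises,0,7.468
Method 4,von_mises,45,6.544
Method 4,von_mises,90,5.479
Method 4,von_mises,135,5.619
Method 1,reaction_force,0,9.878
Method 1,reaction_force,45,6.43
Method 1,reaction_force,90,6.324
Method 1,reaction_force,135,6.354
Method 2,reaction_force,0,9.153
Method 2,reaction_force,45,8.996
Method 2,reaction_force,90,9.256
Method 2,reaction_force,135,8.885
Method 3,reaction_force,0,8.317
Method 3,reaction_force,45,6.333
Method 3,reaction_force,90,6.1732
Method 3,reaction_force,135,6.06
Method 4,reaction_force,0,7.695
Method 4,reaction_force,45,6.808
Method 4,reaction_force,90,6.510
Method 4,reaction_force,135,6.459
Method 1,contact_femur,0,11.391
Method 1,contact_femur,45,7.278
Method 1,contact_femur,90,5.235
Method 1,contact_femur,135,3.914
Method 2,contact_femur,0,13.89
Method 2,contact_femur,45,7.335
Method 2,contact_femur,90,6.302
Method 2,contact_femur,135,6.778
Method 3,contact_femur,0,20.319
Method 3,contact_femur,45,8.87
Method 3,contact_femur,90,5.185
Method 3,contact_femur,135,3.728
Method 4,contact_femur,0,11.853
Method 4,contact_femur,45,9.128
Method 4,contact_femur,90,5.587
Method 4,contact_femur,135,3.612
Method 1,contact_tibia,0,0.66
Method 1,contact_tibia,45,0.907
Method 1,contact_tibia,90,0.432
Method 1,contact_tibia,135,2.651
Method 2,contact_tibia,0,0
Method 2,contact_tibia,45,0.7
Method 2,contact_tibia,90,1.669
Method 2,contact_tibia,135,2.774
Method 3,contact_tibia,0,0
Method 3,contact_tibia,45,0.765
Method 3,contact_tibia,90,0.606
Method 3,contact_tibia,135,2.435
Method 4,contact_tibia,0,0
Method 4,contact_tibia,45,0
Method 4,contact_tibia,90,0.77
Method 4,contact_tibia,135,2.147
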