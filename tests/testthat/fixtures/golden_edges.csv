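label,source,target,valenced
w1,ws_god_action,ss_god_action,yes
w2,ws_god_image,ss_god_image,yes
w3,ws_god_emotion,ss_god_emotion,yes
w4,ws_prayer,ss_prayer,yes
w5,ws_emotion,ss_emotion,yes
w6,ss_emotion,srs_emotion,yes
w7a,ss_god_action,srs_god_action,yes
w7b,srs_god_image,srs_god_action,yes
w7c,srs_god_emotion,srs_god_action,yes
w7d,ps_prayer,srs_god_action,yes
w8a,ss_god_image,srs_god_image,yes
w8b,ss_prayer,srs_god_image,yes
w8c,ps_prayer,srs_god_image,yes
w9a,ss_god_emotion,srs_god_emotion,yes
w9b,srs_god_image,srs_god_emotion,yes
w9c,srs_god_action,srs_god_emotion,yes
w9d,ps_prayer,srs_god_emotion,yes
w10,ps_behaviour,srs_effect,yes
w11a,os_self_action,ps_behaviour,yes
w11b,os_god_action,ps_behaviour,yes
w11c,srs_god_action,ps_behaviour,yes
w11d,fs_emotion,ps_behaviour,yes
w11e,gs,ps_behaviour,yes
w12a,os_self_emotion,ps_emotion,yes
w12b,os_god_emotion,ps_emotion,yes
w12c,srs_god_emotion,ps_emotion,yes
w12d,srs_effect,ps_emotion,yes
w12e,fs_emotion,ps_emotion,yes
w12f,gs,ps_emotion,yes
w13a,srs_god_image,ps_prayer,yes
w13b,srs_god_emotion,ps_prayer,yes
w13c,srs_god_action,ps_prayer,yes
w13d,gs,ps_prayer,yes
w14a,gfs,gs,no
w14b,gs,gs,no
w15a,srs_god_action,gfs,yes
w15b,srs_god_image,gfs,yes
w15c,srs_god_emotion,gfs,yes
w16a,ps_emotion,srs_emotion,yes
w16b,srs_emotion,fs_emotion,yes
w17a,srs_god_action,os_self_action,yes
w17b,srs_effect,os_self_action,yes
w17c,fs_emotion,os_self_action,yes
w18a,srs_god_action,os_god_action,yes
w18b,srs_god_image,os_god_action,yes
w19a,srs_god_emotion,os_self_emotion,yes
w19b,srs_effect,os_self_emotion,yes
w20a,srs_god_image,os_god_emotion,yes
w20b,srs_god_emotion,os_god_emotion,yes
w21a,os_god_action,es_behaviour,yes
w21b,os_self_action,es_behaviour,yes
w21c,ps_behaviour,es_behaviour,yes
w22a,os_self_emotion,es_emotion,yes
w22b,os_god_emotion,es_emotion,yes
w22c,ps_emotion,es_emotion,yes
w23,ps_prayer,es_prayer,yes
w24,es_prayer,ws_prayer,yes
w25,es_emotion,ws_emotion,yes
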